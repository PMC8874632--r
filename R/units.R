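#' Convert an energy value to electronvolts
#'
#' All energies inside the package are carried in eV, the unit every
#' reactivity descriptor and KID index is reported in. Conversion happens
#' once, at ingest.
#'
#' @param value Numeric vector of energies.
#' @param unit One of `"eV"`, `"hartree"`, `"kcal/mol"`.
#' @return Numeric vector in eV.
#' @details Fixed factors: 1 hartree = 27.211386 eV,
#'   1 kcal/mol = 0.0433641 eV. The factors are constants of the package so
#'   that converted values are bit-stable across platforms.
#' @examples
#' convert_energy(1, "hartree")
#' convert_energy(-0.2438, "hartree")
#' @export
convert_energy <- function(value, unit) {
  if (length(unit) != 1L || !is.character(unit)) {
    stop("`unit` must be a single string", call. = FALSE)
  }
  factor <- switch(unit,
    "eV"       = 1,
    "hartree"  = 27.211386,
    "kcal/mol" = 0.0433641,
    stop(sprintf("unknown energy unit '%s' (supported: eV, hartree, kcal/mol)", unit),
         call. = FALSE)
  )
  value * factor
}

# Round half away from zero, the convention the published tables use.
# base::round() rounds half to even, which would print 0.0145 -> 0.014.
round_half_away <- function(x, digits = 3L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
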