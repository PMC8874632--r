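#' Check that two density grids share a common geometry
#'
#' Grid arithmetic (Fukui differences, dual descriptor) requires the two
#' operands to live on the same voxel lattice. Origins and axes must agree
#' to 1e-6 Bohr and shapes exactly; no resampling is attempted between
#' mismatched grids.
#'
#' @param a,b [density_grid()] objects.
#' @param tol Positional tolerance (Bohr).
#' @return A list with `pass` (logical) and `diagnostics` (character
#'   vector naming each failed check).
#' @export
check_grid_compat <- function(a, b, tol = 1e-6) {
  diagnostics <- character()
  if (!identical(as.integer(a$shape), as.integer(b$shape))) {
    dims <- which(a$shape != b$shape)
    diagnostics <- c(diagnostics,
                     sprintf("shape mismatch in dimension(s) %s: %s vs %s",
                             paste(dims, collapse = ","),
                             paste(a$shape, collapse = "x"),
                             paste(b$shape, collapse = "x")))
  }
  d_origin <- max(abs(a$origin - b$origin))
  if (d_origin > tol) {
    diagnostics <- c(diagnostics,
                     sprintf("origin mismatch: max deviation %.3e Bohr (tol %.0e)",
                             d_origin, tol))
  }
  d_axes <- max(abs(a$axes - b$axes))
  if (d_axes > tol) {
    diagnostics <- c(diagnostics,
                     sprintf("axes mismatch: max deviation %.3e Bohr (tol %.0e)",
                             d_axes, tol))
  }
  list(pass = length(diagnostics) == 0L, diagnostics = diagnostics)
}

#' Grid triad of N-1, N, N+1 electron densities
#'
#' @param rho_nminus,rho_n,rho_nplus [density_grid()]s of the cation,
#'   neutral and anion densities on a shared lattice.
#' @return Object of class `grid_triad`.
#' @export
grid_triad <- function(rho_nminus, rho_n, rho_nplus) {
  for (pair in list(list(rho_nminus, "rho_nminus"), list(rho_nplus, "rho_nplus"))) {
    chk <- check_grid_compat(rho_n, pair[[1L]])
    if (!chk$pass) {
      stop(sprintf("grid '%s' incompatible with rho_n: %s", pair[[2L]],
                   paste(chk$diagnostics, collapse = "; ")), call. = FALSE)
    }
  }
  structure(list(rho_nminus = rho_nminus, rho_n = rho_n,
                 rho_nplus = rho_nplus), class = "grid_triad")
}

grid_difference <- function(a, b, what) {
  chk <- check_grid_compat(a, b)
  if (!chk$pass) {
    stop(sprintf("%s: incompatible grids: %s", what,
                 paste(chk$diagnostics, collapse = "; ")), call. = FALSE)
  }
  density_grid(a$origin, a$axes, a$values - b$values, atoms = a$atoms,
               n_electrons_nominal = NA_real_)
}

#' Nucleophilic Fukui function NFF = rho(N+1) - rho(N)
#'
#' Marks the regions that gain density when an electron is added, i.e. the
#' sites most vulnerable to nucleophilic attack. Integrates to 1 (one
#' added electron) up to quadrature error.
#'
#' @param triad A [grid_triad()].
#' @return A [density_grid()] (sign-indefinite values).
#' @export
nucleophilic_fukui <- function(triad) {
  stopifnot(inherits(triad, "grid_triad"))
  grid_difference(triad$rho_nplus, triad$rho_n, "nucleophilic_fukui")
}

#' Electrophilic Fukui function EFF = rho(N) - rho(N-1)
#'
#' Marks the regions that lose density on ionization, i.e. the sites most
#' vulnerable to electrophilic attack. Integrates to 1.
#'
#' @param triad A [grid_triad()].
#' @return A [density_grid()].
#' @export
electrophilic_fukui <- function(triad) {
  stopifnot(inherits(triad, "grid_triad"))
  grid_difference(triad$rho_n, triad$rho_nminus, "electrophilic_fukui")
}

#' Dual descriptor DD = NFF - EFF
#'
#' Two-parabola finite-difference realization of the Fukui-function
#' derivative with respect to electron number. Positive regions are prone
#' to nucleophilic attack, negative regions to electrophilic attack; the
#' grid integrates to ~0 since both Fukui functions carry one electron.
#'
#' @param nff,eff Fukui-function grids on a shared lattice (typically from
#'   [nucleophilic_fukui()] / [electrophilic_fukui()]).
#' @return A [density_grid()].
#' @export
dual_descriptor <- function(nff, eff) {
  grid_difference(nff, eff, "dual_descriptor")
}

#' Condensed (per-atom) Fukui functions from atomic-charge triads
#'
#' Finite-difference condensation onto atoms from population-analysis
#' charges (e.g. Hirshfeld) of the three species:
#' f+_k = q_k(N) - q_k(N+1), f-_k = q_k(N-1) - q_k(N),
#' dd_k = f+_k - f-_k. With charges that sum correctly, each Fukui vector
#' sums to 1.
#'
#' @param atom_labels Character vector of atom labels.
#' @param q_nminus,q_n,q_nplus Numeric vectors of per-atom charges (e) for
#'   the N-1, N, N+1 electron species, aligned with `atom_labels`.
#' @param charge_sum_tol Tolerance (e) on the requirement that total
#'   charges of successive species differ by 1.
#' @return Data frame with columns `atom`, `f_plus`, `f_minus`, `dd`.
#' @export
condensed_fukui <- function(atom_labels, q_nminus, q_n, q_nplus,
                            charge_sum_tol = 0.05) {
  n <- length(atom_labels)
  if (length(q_nminus) != n || length(q_n) != n || length(q_nplus) != n) {
    stop("charge vectors must all match the number of atom labels",
         call. = FALSE)
  }
  d_cat <- sum(q_nminus) - sum(q_n)
  d_an <- sum(q_n) - sum(q_nplus)
  if (abs(d_cat - 1) > charge_sum_tol || abs(d_an - 1) > charge_sum_tol) {
    stop(sprintf("species total charges must differ by 1 e (found %+.3f and %+.3f)",
                 d_cat, d_an), call. = FALSE)
  }
  f_plus <- q_n - q_nplus
  f_minus <- q_nminus - q_n
  data.frame(atom = atom_labels, f_plus = f_plus, f_minus = f_minus,
             dd = f_plus - f_minus, stringsAsFactors = FALSE)
}
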