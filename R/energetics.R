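#' Species record: one electronic state of one molecule
#'
#' A species is the molecule at a fixed electron count: the neutral
#' (N electrons), the radical cation (N-1, doublet) or the radical anion
#' (N+1, doublet). The record carries the ground-state total energy and,
#' where meaningful, orbital energies: HOMO/LUMO for the neutral, the SOMO
#' for the radical anion.
#'
#' @param molecule_id Molecule label.
#' @param charge Integer charge in elementary-charge units.
#' @param multiplicity Positive integer spin multiplicity.
#' @param total_energy Ground-state total energy (eV); may be `NA` when only
#'   orbital-derived descriptors are wanted.
#' @param homo,lumo,somo Orbital energies (eV) or `NA`.
#' @return An object of class `species_record`.
#' @export
species_record <- function(molecule_id, charge, multiplicity,
                           total_energy = NA_real_,
                           homo = NA_real_, lumo = NA_real_, somo = NA_real_) {
  stopifnot(is.character(molecule_id), length(molecule_id) == 1L)
  charge <- as.integer(charge)
  multiplicity <- as.integer(multiplicity)
  if (is.na(multiplicity) || multiplicity < 1L) {
    stop("multiplicity must be a positive integer", call. = FALSE)
  }
  for (nm in c("total_energy", "homo", "lumo", "somo")) {
    v <- get(nm)
    if (!is.na(v) && !is.finite(v)) {
      stop(sprintf("%s must be finite or NA", nm), call. = FALSE)
    }
  }
  if (charge == 0L && !is.na(homo) && !is.na(lumo) && homo >= lumo) {
    stop(sprintf("neutral species '%s': HOMO (%.4f) must lie below LUMO (%.4f)",
                 molecule_id, homo, lumo), call. = FALSE)
  }
  structure(
    list(molecule_id = molecule_id, charge = charge,
         multiplicity = multiplicity,
         total_energy = as.numeric(total_energy),
         homo = as.numeric(homo), lumo = as.numeric(lumo),
         somo = as.numeric(somo)),
    class = "species_record"
  )
}

#' Solvent specification
#'
#' @param name Solvent label (e.g. `"H2O"`, `"Gas"`).
#' @param dielectric Dielectric constant, >= 1 (1 = vacuum/gas phase).
#' @return An object of class `solvent_spec`.
#' @export
solvent_spec <- function(name, dielectric) {
  stopifnot(is.character(name), length(name) == 1L)
  dielectric <- as.numeric(dielectric)
  if (!is.finite(dielectric) || dielectric < 1) {
    stop("dielectric constant must be >= 1", call. = FALSE)
  }
  structure(list(name = name, dielectric = dielectric), class = "solvent_spec")
}

#' Molecule energetics: the N, N-1, N+1 species triad
#'
#' Bundles the three electronic species of one molecule computed with one
#' density functional in one solvent. The radical cation and anion are
#' doublets; the neutral is the reference for all frontier-orbital
#' descriptors.
#'
#' @param molecule_id Molecule label shared by the three species.
#' @param functional Density functional label (e.g. `"MN12SX"`).
#' @param solvent A [solvent_spec()].
#' @param neutral,cation,anion [species_record()]s with charges 0, +1, -1;
#'   `cation` and `anion` may be `NULL` for a partial triad (global
#'   descriptors need only the neutral; KID total-energy indices refuse
#'   partial triads).
#' @return An object of class `molecule_energetics` with a logical
#'   `partial` element.
#' @export
molecule_energetics <- function(molecule_id, functional, solvent,
                                neutral, cation = NULL, anion = NULL) {
  stopifnot(inherits(solvent, "solvent_spec"),
            inherits(neutral, "species_record"))
  if (neutral$charge != 0L) stop("`neutral` must have charge 0", call. = FALSE)
  for (sp in list(cation, anion)) {
    if (!is.null(sp) && !inherits(sp, "species_record")) {
      stop("cation/anion must be species_record or NULL", call. = FALSE)
    }
  }
  if (!is.null(cation) && cation$charge != 1L) {
    stop("`cation` must have charge +1", call. = FALSE)
  }
  if (!is.null(anion) && anion$charge != -1L) {
    stop("`anion` must have charge -1", call. = FALSE)
  }
  ids <- c(neutral$molecule_id,
           if (!is.null(cation)) cation$molecule_id,
           if (!is.null(anion)) anion$molecule_id)
  if (!all(ids == molecule_id)) {
    stop("all species must share the triad's molecule_id", call. = FALSE)
  }
  structure(
    list(molecule_id = molecule_id, functional = functional,
         solvent = solvent, neutral = neutral, cation = cation, anion = anion,
         partial = is.null(cation) || is.null(anion)),
    class = "molecule_energetics"
  )
}

#' @export
print.molecule_energetics <- function(x, ...) {
  cat(sprintf("<molecule_energetics> %s [%s / %s, eps = %.4g]%s\n",
              x$molecule_id, x$functional, x$solvent$name,
              x$solvent$dielectric, if (x$partial) " (partial)" else ""))
  sp <- function(s, lbl) {
    if (is.null(s)) return(invisible())
    cat(sprintf("  %-7s q=%+d 2S+1=%d  E=%s  HOMO=%s LUMO=%s SOMO=%s\n",
                lbl, s$charge, s$multiplicity,
                fmt_or_na(s$total_energy), fmt_or_na(s$homo),
                fmt_or_na(s$lumo), fmt_or_na(s$somo)))
  }
  sp(x$neutral, "neutral"); sp(x$cation, "cation"); sp(x$anion, "anion")
  invisible(x)
}

fmt_or_na <- function(x) if (is.na(x)) "NA" else sprintf("%.4f", x)

energetics_columns <- c("molecule_id", "functional", "solvent_name",
                        "solvent_dielectric", "charge", "multiplicity",
                        "total_energy", "energy_unit")

#' Read a per-species energetics table
#'
#' The canonical input schema is delimited text with a header and one row
#' per electronic species. Required columns: `molecule_id`, `functional`,
#' `solvent_name`, `solvent_dielectric`, `charge`, `multiplicity`,
#' `total_energy`, `energy_unit`; optional: `homo`, `lumo`, `somo` (in
#' `energy_unit`). Rows are grouped into (molecule, functional, solvent)
#' triads; all energies are converted to eV at ingest.
#'
#' @param source Path to a delimited text file.
#' @param sep Field separator (default `","`).
#' @return A list of [molecule_energetics()] triads, named by
#'   `molecule_id`; triads missing the cation and/or anion carry
#'   `partial = TRUE`.
#' @seealso [write_energetics_table()]
#' @export
read_energetics_table <- function(source, sep = ",") {
  df <- utils::read.table(source, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, strip.white = TRUE)
  if (nrow(df) == 0L) return(list())
  missing_cols <- setdiff(energetics_columns, names(df))
  if (length(missing_cols) > 0L) {
    stop(sprintf("energetics table is missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  for (opt in c("homo", "lumo", "somo")) {
    if (!opt %in% names(df)) df[[opt]] <- NA_real_
  }

  num_cols <- c("solvent_dielectric", "charge", "multiplicity",
                "total_energy", "homo", "lumo", "somo")
  for (cl in num_cols) {
    raw <- df[[cl]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & raw != "" & is.na(val) &
                   !(cl %in% c("total_energy", "homo", "lumo", "somo") &
                       toupper(trimws(as.character(raw))) == "NA"))
    if (length(bad) > 0L) {
      stop(sprintf("malformed value '%s' in column '%s' at data row %d",
                   raw[bad[1L]], cl, bad[1L]), call. = FALSE)
    }
    df[[cl]] <- val
  }

  key <- paste(df$molecule_id, df$functional, df$solvent_name, df$charge,
               sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE][1L, ]
    stop(sprintf("duplicate species row: molecule '%s', functional '%s', solvent '%s', charge %+d",
                 d$molecule_id, d$functional, d$solvent_name, d$charge),
         call. = FALSE)
  }

  # energies to eV, row by row (unit may differ per row)
  for (i in seq_len(nrow(df))) {
    u <- df$energy_unit[i]
    for (cl in c("total_energy", "homo", "lumo", "somo")) {
      if (!is.na(df[[cl]][i])) df[[cl]][i] <- convert_energy(df[[cl]][i], u)
    }
  }

  triad_key <- paste(df$molecule_id, df$functional, df$solvent_name, sep = "\r")
  out <- list()
  for (k in unique(triad_key)) {
    rows <- df[triad_key == k, , drop = FALSE]
    pick <- function(q) {
      j <- which(rows$charge == q)
      if (length(j) == 0L) return(NULL)
      r <- rows[j, ]
      species_record(r$molecule_id, r$charge, r$multiplicity,
                     total_energy = r$total_energy,
                     homo = r$homo, lumo = r$lumo, somo = r$somo)
    }
    neutral <- pick(0L)
    if (is.null(neutral)) {
      stop(sprintf("triad '%s' has no neutral (charge 0) species row",
                   rows$molecule_id[1L]), call. = FALSE)
    }
    out[[length(out) + 1L]] <- molecule_energetics(
      rows$molecule_id[1L], rows$functional[1L],
      solvent_spec(rows$solvent_name[1L], rows$solvent_dielectric[1L]),
      neutral = neutral, cation = pick(1L), anion = pick(-1L)
    )
  }
  names(out) <- vapply(out, `[[`, character(1L), "molecule_id")
  out
}

#' Write molecule triads back to the energetics schema
#'
#' Inverse of [read_energetics_table()]; all energies are written in eV.
#'
#' @param triads List of [molecule_energetics()] objects.
#' @param path Output file path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_energetics_table <- function(triads, path, sep = ",") {
  rows <- list()
  for (tr in triads) {
    for (sp in list(tr$neutral, tr$cation, tr$anion)) {
      if (is.null(sp)) next
      rows[[length(rows) + 1L]] <- data.frame(
        molecule_id = sp$molecule_id, functional = tr$functional,
        solvent_name = tr$solvent$name,
        solvent_dielectric = tr$solvent$dielectric,
        charge = sp$charge, multiplicity = sp$multiplicity,
        total_energy = sp$total_energy, energy_unit = "eV",
        homo = sp$homo, lumo = sp$lumo, somo = sp$somo,
        stringsAsFactors = FALSE
      )
    }
  }
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
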