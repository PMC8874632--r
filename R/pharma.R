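#' Hardness-based pKa QSAR
#'
#' Linear QSAR relating the predicted pKa of a peptide to its global
#' hardness: pKa = 16.3088 - 0.8268 eta (eta in eV). The relationship was
#' calibrated on amino acids and small peptides; for large cyclopeptides
#' it extrapolates and should be read as a trend estimate.
#'
#' @param eta Global hardness (eV), positive.
#' @param intercept,slope QSAR coefficients (defaults as published).
#' @return Predicted pKa (vectorised over `eta`).
#' @export
predict_pka <- function(eta, intercept = 16.3088, slope = -0.8268) {
  stopifnot(all(is.finite(eta)))
  intercept + slope * eta
}

#' Classify a bioactivity score into activity bands
#'
#' Scores from target-similarity predictors are interpreted as: active
#' above 0, inactive below -5.0, moderately active between (both
#' boundaries inclusive to the middle band).
#'
#' @param score Numeric bioactivity score(s).
#' @return `"active"`, `"moderately_active"` or `"inactive"` (vectorised).
#' @export
classify_bioactivity <- function(score) {
  stopifnot(all(is.finite(score)))
  ifelse(score > 0, "active",
         ifelse(score >= -5.0, "moderately_active", "inactive"))
}

bioactivity_targets <- c("gpcr_ligand", "ion_channel_modulator",
                         "nuclear_receptor_ligand", "kinase_inhibitor",
                         "protease_inhibitor", "enzyme_inhibitor")

#' Read a bioactivity score table
#'
#' Delimited text with a `molecule_id` column and the six target-class
#' score columns: `gpcr_ligand`, `ion_channel_modulator`,
#' `nuclear_receptor_ligand`, `kinase_inhibitor`, `protease_inhibitor`,
#' `enzyme_inhibitor`.
#'
#' @param source Path to the table.
#' @param sep Field separator.
#' @return Data frame of scores, one row per molecule.
#' @export
read_bioactivity_table <- function(source, sep = ",") {
  df <- utils::read.table(source, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, strip.white = TRUE)
  missing_cols <- setdiff(c("molecule_id", bioactivity_targets), names(df))
  if (length(missing_cols) > 0L) {
    stop(sprintf("bioactivity table missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  df
}

#' Band classification of a bioactivity score table
#'
#' @param scores Data frame from [read_bioactivity_table()].
#' @return Data frame of bands (same layout, scores replaced by bands).
#' @export
bioactivity_bands <- function(scores) {
  out <- scores[, c("molecule_id", bioactivity_targets), drop = FALSE]
  for (tg in bioactivity_targets) out[[tg]] <- classify_bioactivity(scores[[tg]])
  out
}

admet_vocabulary <- c(
  "HI Absorption", "BBB Permeability", "Caco-2",
  "P-gp Substrate", "P-gp Inhibitor",
  "CYP2C9 Substrate", "CYP2D6 Substrate", "CYP3A4 Substrate",
  "CYP1A2 Inhibitor", "CYP2C19 Inhibitor", "CYP2C9 Inhibitor",
  "CYP2D6 Inhibitor", "CYP3A4 Inhibitor",
  "OCT2 Substrate", "AMES Toxicity", "hERG Inhibitor",
  "Hepatotoxicity", "Skin Sensitization"
)

#' Read an ADMET +/- matrix
#'
#' Delimited text with a `property` column (names from the fixed 18-entry
#' ADMET vocabulary) and one `+`/`-` column per molecule.
#'
#' @param source Path to the table.
#' @param sep Field separator.
#' @return Logical matrix, properties x molecules (`TRUE` = `+`).
#' @export
read_admet_table <- function(source, sep = ",") {
  df <- utils::read.table(source, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          strip.white = TRUE)
  stopifnot("property" %in% names(df))
  unknown <- setdiff(df$property, admet_vocabulary)
  if (length(unknown) > 0L) {
    stop(sprintf("unknown ADMET property name(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  mols <- setdiff(names(df), "property")
  m <- matrix(NA, nrow(df), length(mols),
              dimnames = list(df$property, mols))
  for (mol in mols) {
    tok <- trimws(df[[mol]])
    bad <- !tok %in% c("+", "-")
    if (any(bad)) {
      stop(sprintf("ADMET token '%s' for %s / %s is not '+' or '-'",
                   tok[bad][1L], df$property[bad][1L], mol), call. = FALSE)
    }
    m[, mol] <- tok == "+"
  }
  m
}

#' Summarise an ADMET matrix across molecules
#'
#' Partitions every property into exactly one of: uniformly positive,
#' uniformly negative, or mixed across the molecule panel, and names the
#' positive molecules for mixed properties.
#'
#' @param flags Logical matrix from [read_admet_table()].
#' @return Data frame with columns `property`, `status`
#'   (`"uniform_positive"`, `"uniform_negative"`, `"mixed"`) and
#'   `positive_molecules` (comma-joined labels, `""` if none).
#' @export
assemble_admet_report <- function(flags) {
  unknown <- setdiff(rownames(flags), admet_vocabulary)
  if (length(unknown) > 0L) {
    stop(sprintf("unknown ADMET property name(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  status <- apply(flags, 1L, function(v) {
    if (all(v)) "uniform_positive" else if (!any(v)) "uniform_negative" else "mixed"
  })
  pos <- apply(flags, 1L, function(v) paste(colnames(flags)[v], collapse = ","))
  data.frame(property = rownames(flags), status = unname(status),
             positive_molecules = unname(pos), stringsAsFactors = FALSE)
}

#' Assemble per-molecule pharmacology profiles
#'
#' Combines the hardness-based pKa prediction with bioactivity bands and
#' ADMET flags into one profile record per molecule.
#'
#' @param descriptors Data frame from [global_descriptor_table()] (needs
#'   `molecule_id` and `eta`).
#' @param scores Optional data frame from [read_bioactivity_table()].
#' @param admet Optional logical matrix from [read_admet_table()].
#' @return Named list of `pharma_profile` objects.
#' @export
pharma_profiles <- function(descriptors, scores = NULL, admet = NULL) {
  bands <- if (!is.null(scores)) bioactivity_bands(scores) else NULL
  out <- lapply(seq_len(nrow(descriptors)), function(i) {
    id <- descriptors$molecule_id[i]
    p <- list(molecule_id = id,
              pka_predicted = predict_pka(descriptors$eta[i]),
              bioactivity_scores = NULL, bioactivity_bands = NULL,
              admet_flags = NULL)
    if (!is.null(scores) && id %in% scores$molecule_id) {
      j <- match(id, scores$molecule_id)
      p$bioactivity_scores <- unlist(scores[j, bioactivity_targets])
      p$bioactivity_bands <- unlist(bands[j, bioactivity_targets])
    }
    if (!is.null(admet) && id %in% colnames(admet)) {
      p$admet_flags <- admet[, id]
    }
    structure(p, class = "pharma_profile")
  })
  names(out) <- descriptors$molecule_id
  out
}

#' @export
print.pharma_profile <- function(x, ...) {
  cat(sprintf("<pharma_profile> %s  pKa(QSAR) = %.2f\n",
              x$molecule_id, x$pka_predicted))
  if (!is.null(x$bioactivity_bands)) {
    cat("  bioactivity:",
        paste(sprintf("%s=%s", names(x$bioactivity_bands), x$bioactivity_bands),
              collapse = " "), "\n")
  }
  if (!is.null(x$admet_flags)) {
    cat(sprintf("  ADMET: %d/%d positive\n", sum(x$admet_flags),
                length(x$admet_flags)))
  }
  invisible(x)
}
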