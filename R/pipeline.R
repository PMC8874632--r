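#' Path to a shipped example data file
#'
#' @param file File name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return Full path (or file listing).
#' @export
cdft_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "cdftpept")))
  }
  path <- system.file("extdata", file, package = "cdftpept")
  if (path == "") stop(sprintf("no example file '%s'", file), call. = FALSE)
  path
}

format_report_table <- function(df, digits) {
  for (nm in names(digits)) {
    if (nm %in% names(df)) {
      df[[nm]] <- sprintf(paste0("%.", digits[[nm]], "f"),
                          round_half_away(df[[nm]], digits[[nm]]))
    }
  }
  df
}

#' Run the full reactivity-and-pharmacology pipeline
#'
#' Orchestrates one end-to-end analysis: ingest an energetics table,
#' compute the global descriptor table and scale bands, compute whatever
#' KID indices the records support (Delta(SL) needs the anion SOMO; J(I)
#' and J(A) need cation/anion total energies), predict pKas, and — when
#' score/ADMET tables are supplied — attach bioactivity bands and the
#' ADMET summary. Failures are per-molecule: a record that cannot enter a
#' table is logged and skipped, and the remaining molecules proceed.
#'
#' @param energetics Path to an energetics table
#'   (see [read_energetics_table()]) or a list of triads.
#' @param config A [reactivity_config()].
#' @param scores Optional path to a bioactivity score table.
#' @param admet Optional path to an ADMET matrix.
#' @param output_dir Optional directory; when given, each table is also
#'   written as a delimited text file with report rounding (3 decimals for
#'   descriptors and KID indices, 2 for pKa).
#' @return List of class `cdft_pipeline_result`: `descriptors`, `kid`,
#'   `pka`, `bioactivity_bands`, `admet_summary`, `profiles`, `log`
#'   (character vector of per-stage messages), `n_failed`.
#' @export
run_cdft_pipeline <- function(energetics, config = reactivity_config(),
                              scores = NULL, admet = NULL,
                              output_dir = NULL) {
  triads <- if (is.character(energetics)) read_energetics_table(energetics)
            else energetics
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))
  note("pipeline start: %d molecule triad(s)", length(triads))
  n_failed <- 0L

  # global descriptors (needs neutral frontier orbitals only)
  ok <- logical(length(triads))
  for (i in seq_along(triads)) {
    g <- tryCatch(global_descriptor_set(triads[[i]], config),
                  error = function(e) e)
    if (inherits(g, "error")) {
      note("global_descriptors: %s: SKIPPED (%s)", triads[[i]]$molecule_id,
           conditionMessage(g))
      n_failed <- n_failed + 1L
    } else {
      ok[i] <- TRUE
    }
  }
  descriptors <- global_descriptor_table(triads[ok], config)
  note("global_descriptors: %d of %d molecules", nrow(descriptors),
       length(triads))

  # KID indices: compute per component, NA where the record lacks inputs
  kid_rows <- lapply(triads, function(tr) {
    val <- function(f) tryCatch(f(tr), error = function(e) NA_real_)
    ji <- val(j_ionization); ja <- val(j_affinity); dsl <- val(delta_sl)
    jhl <- if (!is.na(ji) && !is.na(ja)) j_hl(ji, ja) else NA_real_
    g <- if (!anyNA(c(ji, ja, jhl, dsl))) gkd(ji, ja, jhl, dsl) else NA_real_
    data.frame(molecule_id = tr$molecule_id, j_i = ji, j_a = ja, j_hl = jhl,
               delta_sl = dsl, gkd = g, stringsAsFactors = FALSE)
  })
  kid <- if (length(kid_rows) > 0L) {
    k <- do.call(rbind, kid_rows)
    k <- k[order(k$molecule_id), , drop = FALSE]
    rownames(k) <- NULL
    k
  } else {
    data.frame(molecule_id = character(), j_i = numeric(), j_a = numeric(),
               j_hl = numeric(), delta_sl = numeric(), gkd = numeric(),
               stringsAsFactors = FALSE)
  }
  if (nrow(kid) > 0L && anyNA(kid$gkd)) {
    note("kid: %d molecule(s) lack total energies and/or SOMO; partial KID columns",
         sum(is.na(kid$gkd)))
  }

  pka <- if (nrow(descriptors) > 0L) {
    data.frame(molecule_id = descriptors$molecule_id,
               pka_predicted = predict_pka(descriptors$eta),
               stringsAsFactors = FALSE)
  } else {
    data.frame(molecule_id = character(), pka_predicted = numeric(),
               stringsAsFactors = FALSE)
  }

  score_df <- if (is.character(scores)) read_bioactivity_table(scores) else scores
  admet_m <- if (is.character(admet)) read_admet_table(admet) else admet
  bands <- if (!is.null(score_df)) bioactivity_bands(score_df) else NULL
  admet_summary <- if (!is.null(admet_m)) assemble_admet_report(admet_m) else NULL
  profiles <- if (nrow(descriptors) > 0L) {
    pharma_profiles(descriptors, scores = score_df, admet = admet_m)
  } else list()

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(df, name, digits) {
      utils::write.table(format_report_table(df, digits),
                         file.path(output_dir, name),
                         sep = ",", row.names = FALSE, quote = FALSE)
    }
    d3 <- 3L
    wr(descriptors, "global_descriptors.csv",
       list(chi = d3, eta = d3, omega = d3, softness = d3, nu = d3,
            omega_minus = d3, omega_plus = d3, net_electrophilicity = d3))
    wr(kid, "kid_indices.csv",
       list(j_i = d3, j_a = d3, j_hl = d3, delta_sl = d3, gkd = d3))
    wr(pka, "pka_predictions.csv", list(pka_predicted = 2L))
    if (!is.null(bands)) wr(bands, "bioactivity_bands.csv", list())
    if (!is.null(admet_summary)) wr(admet_summary, "admet_summary.csv", list())
    note("tables written to %s", output_dir)
  }

  note("pipeline done: %d failure(s)", n_failed)
  structure(
    list(descriptors = descriptors, kid = kid, pka = pka,
         bioactivity_bands = bands, admet_summary = admet_summary,
         profiles = profiles, log = log, n_failed = n_failed),
    class = "cdft_pipeline_result"
  )
}

#' @export
print.cdft_pipeline_result <- function(x, ...) {
  cat("<cdft_pipeline_result>\n")
  cat(sprintf("  %d molecule(s) in descriptor table, %d failed\n",
              nrow(x$descriptors), x$n_failed))
  for (l in x$log) cat("  log:", l, "\n")
  invisible(x)
}
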