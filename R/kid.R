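#' Ionization-side Koopmans deviation J(I)
#'
#' Deviation of the neutral's HOMO eigenvalue from minus the vertical
#' ionization energy: J(I) = |eH + Egs(N-1) - Egs(N)|. Zero for a
#' functional exactly satisfying the ionization energy theorem.
#'
#' @param triad A [molecule_energetics()] with neutral HOMO and the
#'   neutral/cation ground-state total energies.
#' @return J(I) (eV), non-negative.
#' @export
j_ionization <- function(triad) {
  stopifnot(inherits(triad, "molecule_energetics"))
  if (is.null(triad$cation) || is.na(triad$cation$total_energy) ||
      is.na(triad$neutral$total_energy)) {
    stop(sprintf("molecule '%s': cation and neutral total energies required for J(I)",
                 triad$molecule_id), call. = FALSE)
  }
  if (is.na(triad$neutral$homo)) {
    stop(sprintf("molecule '%s': neutral HOMO required for J(I)",
                 triad$molecule_id), call. = FALSE)
  }
  abs(triad$neutral$homo + triad$cation$total_energy - triad$neutral$total_energy)
}

#' Affinity-side Koopmans deviation J(A)
#'
#' J(A) = |eL + Egs(N) - Egs(N+1)|: deviation of the neutral's LUMO
#' eigenvalue from minus the vertical electron affinity.
#'
#' @param triad A [molecule_energetics()] with neutral LUMO and the
#'   neutral/anion ground-state total energies.
#' @return J(A) (eV), non-negative.
#' @export
j_affinity <- function(triad) {
  stopifnot(inherits(triad, "molecule_energetics"))
  if (is.null(triad$anion) || is.na(triad$anion$total_energy) ||
      is.na(triad$neutral$total_energy)) {
    stop(sprintf("molecule '%s': anion and neutral total energies required for J(A)",
                 triad$molecule_id), call. = FALSE)
  }
  if (is.na(triad$neutral$lumo)) {
    stop(sprintf("molecule '%s': neutral LUMO required for J(A)",
                 triad$molecule_id), call. = FALSE)
  }
  abs(triad$neutral$lumo + triad$neutral$total_energy - triad$anion$total_energy)
}

#' Combined frontier deviation J(HL)
#'
#' Euclidean norm of the two one-sided deviations:
#' J(HL) = sqrt(J(I)^2 + J(A)^2).
#'
#' @param j_i,j_a Non-negative deviations (eV).
#' @return J(HL) (eV).
#' @export
j_hl <- function(j_i, j_a) {
  stopifnot(all(j_i >= 0), all(j_a >= 0))
  sqrt(j_i^2 + j_a^2)
}

#' SOMO-LUMO deviation Delta(SL)
#'
#' |eSOMO(anion) - eL(neutral)|: the radical anion's singly occupied
#' orbital should coincide with the neutral's LUMO when the derivative
#' discontinuity is negligible. The anion SOMO convention follows the
#' published tables (the SOMO column is the HOMO of the anion).
#'
#' @param triad A [molecule_energetics()] with neutral LUMO and anion SOMO.
#' @return Delta(SL) (eV), non-negative.
#' @export
delta_sl <- function(triad) {
  stopifnot(inherits(triad, "molecule_energetics"))
  if (is.null(triad$anion) || is.na(triad$anion$somo)) {
    stop(sprintf("molecule '%s': anion SOMO required for Delta(SL)",
                 triad$molecule_id), call. = FALSE)
  }
  if (is.na(triad$neutral$lumo)) {
    stop(sprintf("molecule '%s': neutral LUMO required for Delta(SL)",
                 triad$molecule_id), call. = FALSE)
  }
  abs(triad$anion$somo - triad$neutral$lumo)
}

#' Global KID descriptor
#'
#' GKD = sqrt(J(I)^2 + J(A)^2 + J(HL)^2 + Delta(SL)^2). Because
#' J(HL)^2 = J(I)^2 + J(A)^2 by construction, GKD equals
#' sqrt(2 J(HL)^2 + Delta(SL)^2); the deliberate double counting is part
#' of the descriptor's definition and is kept as such. Zero for the exact
#' functional.
#'
#' @param j_i,j_a,j_hl,d_sl Non-negative deviation components (eV).
#' @return GKD (eV).
#' @seealso [gkd_nonredundant()] for the variant without double counting.
#' @export
gkd <- function(j_i, j_a, j_hl, d_sl) {
  stopifnot(all(j_i >= 0), all(j_a >= 0), all(j_hl >= 0), all(d_sl >= 0))
  sqrt(j_i^2 + j_a^2 + j_hl^2 + d_sl^2)
}

#' Non-redundant aggregate KID deviation
#'
#' sqrt(J(I)^2 + J(A)^2 + Delta(SL)^2): the aggregate without the J(HL)
#' double counting. Offered alongside [gkd()] for sensitivity analysis; it
#' is never substituted for GKD.
#'
#' @inheritParams gkd
#' @return Aggregate deviation (eV).
#' @export
gkd_nonredundant <- function(j_i, j_a, d_sl) {
  stopifnot(all(j_i >= 0), all(j_a >= 0), all(d_sl >= 0))
  sqrt(j_i^2 + j_a^2 + d_sl^2)
}

#' Full KID descriptor set for one molecule
#'
#' @param triad A complete [molecule_energetics()] (neutral HOMO/LUMO,
#'   cation/anion total energies, anion SOMO).
#' @return Object of class `kid_descriptor_set`: `molecule_id`, `j_i`,
#'   `j_a`, `j_hl`, `delta_sl`, `gkd` (all eV).
#' @export
kid_descriptor_set <- function(triad) {
  ji <- j_ionization(triad)
  ja <- j_affinity(triad)
  jhl <- j_hl(ji, ja)
  dsl <- delta_sl(triad)
  structure(
    list(molecule_id = triad$molecule_id, j_i = ji, j_a = ja, j_hl = jhl,
         delta_sl = dsl, gkd = gkd(ji, ja, jhl, dsl)),
    class = "kid_descriptor_set"
  )
}

#' KID table for a set of molecules
#'
#' @param triads List of complete [molecule_energetics()] objects.
#' @return Data frame, one row per molecule, ordered by molecule id.
#' @export
kid_table <- function(triads) {
  rows <- lapply(triads, function(tr) {
    k <- kid_descriptor_set(tr)
    data.frame(molecule_id = k$molecule_id, j_i = k$j_i, j_a = k$j_a,
               j_hl = k$j_hl, delta_sl = k$delta_sl, gkd = k$gkd,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$molecule_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate per-molecule GKD into a functional-by-solvent benchmark
#'
#' Unweighted arithmetic mean of GKD over the molecules in each
#' (functional, solvent) cell, the aggregation behind a benchmark matrix of
#' functional quality across solvents.
#'
#' @param records Data frame with columns `functional`, `solvent_name`,
#'   `solvent_dielectric`, `gkd` (one row per molecule per cell).
#' @return Data frame of cells: `functional`, `solvent_name`,
#'   `solvent_dielectric`, `mean_gkd`, `n_molecules`; sorted by functional
#'   then descending dielectric.
#' @export
aggregate_benchmark <- function(records) {
  empty <- data.frame(functional = character(), solvent_name = character(),
                      solvent_dielectric = numeric(), mean_gkd = numeric(),
                      n_molecules = integer(), stringsAsFactors = FALSE)
  if (is.null(records) || nrow(records) == 0L) return(empty)
  stopifnot(all(c("functional", "solvent_name", "solvent_dielectric", "gkd")
                %in% names(records)))
  agg <- stats::aggregate(gkd ~ functional + solvent_name + solvent_dielectric,
                          data = records, FUN = mean)
  n <- stats::aggregate(gkd ~ functional + solvent_name + solvent_dielectric,
                        data = records, FUN = length)
  out <- data.frame(functional = agg$functional,
                    solvent_name = agg$solvent_name,
                    solvent_dielectric = agg$solvent_dielectric,
                    mean_gkd = agg$gkd, n_molecules = as.integer(n$gkd),
                    stringsAsFactors = FALSE)
  out <- out[order(out$functional, -out$solvent_dielectric), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank density functionals by mean GKD in one solvent
#'
#' Smallest mean GKD (best fulfilment of the ionization energy theorem)
#' first; ties broken alphabetically for determinism.
#'
#' @param cells Benchmark cells as produced by [aggregate_benchmark()] or
#'   [read_benchmark_table()].
#' @param solvent Solvent name to rank within.
#' @return Character vector of functional labels, best first.
#' @export
rank_functionals <- function(cells, solvent) {
  sub <- cells[cells$solvent_name == solvent, , drop = FALSE]
  if (nrow(sub) == 0L) {
    stop(sprintf("solvent '%s' not present in benchmark cells", solvent),
         call. = FALSE)
  }
  sub$functional[order(sub$mean_gkd, sub$functional)]
}

#' Read a wide benchmark matrix (solvents x functionals)
#'
#' Parses the conventional benchmark layout: one row per solvent with an
#' `inv_dielectric` (1/eps) column followed by one mean-GKD column per
#' functional.
#'
#' @param source Path to a delimited file with columns `solvent_name`,
#'   `inv_dielectric`, then functional labels.
#' @param sep Field separator.
#' @param n_molecules Number of molecules each mean was taken over
#'   (metadata carried into the cells).
#' @return Benchmark cells in the [aggregate_benchmark()] layout.
#' @export
read_benchmark_table <- function(source, sep = ",", n_molecules = NA_integer_) {
  df <- utils::read.table(source, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          strip.white = TRUE)
  stopifnot(all(c("solvent_name", "inv_dielectric") %in% names(df)))
  funs <- setdiff(names(df), c("solvent_name", "inv_dielectric"))
  cells <- do.call(rbind, lapply(funs, function(f) {
    data.frame(functional = f, solvent_name = df$solvent_name,
               solvent_dielectric = 1 / df$inv_dielectric,
               mean_gkd = as.numeric(df[[f]]),
               n_molecules = as.integer(n_molecules),
               stringsAsFactors = FALSE)
  }))
  cells <- cells[order(cells$functional, -cells$solvent_dielectric), ,
                 drop = FALSE]
  rownames(cells) <- NULL
  cells
}
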