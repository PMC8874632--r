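#' Reactivity configuration
#'
#' Holds the nucleophilicity origin and the band cutoffs of the published
#' electrophilicity and nucleophilicity scales.
#'
#' @param tce_homo_reference HOMO energy (eV) of tetracyanoethylene (TCE),
#'   the conventional origin of the nucleophilicity scale. The default,
#'   -8.793 eV, is a derived constant back-computed from the shipped
#'   Veraguamide tables (MN12SX/Def2TZVP in water); it is model-chemistry
#'   dependent and should be overridden when working with another
#'   functional or solvent.
#' @param electrophile_strong_cutoff,electrophile_marginal_cutoff Cutoffs
#'   (eV) of the electrophilicity scale: strong above 1.5, marginal below
#'   0.8, moderate between.
#' @param nucleophile_strong_cutoff,nucleophile_marginal_cutoff Cutoffs
#'   (eV) of the TCE-referenced nucleophilicity scale: strong above 3.0,
#'   marginal at or below 2.0.
#' @return An object of class `reactivity_config`.
#' @export
reactivity_config <- function(tce_homo_reference = -8.793,
                              electrophile_strong_cutoff = 1.5,
                              electrophile_marginal_cutoff = 0.8,
                              nucleophile_strong_cutoff = 3.0,
                              nucleophile_marginal_cutoff = 2.0) {
  if (electrophile_strong_cutoff <= electrophile_marginal_cutoff ||
      nucleophile_strong_cutoff <= nucleophile_marginal_cutoff) {
    stop("strong cutoffs must exceed marginal cutoffs", call. = FALSE)
  }
  structure(
    list(tce_homo_reference = tce_homo_reference,
         electrophile_strong_cutoff = electrophile_strong_cutoff,
         electrophile_marginal_cutoff = electrophile_marginal_cutoff,
         nucleophile_strong_cutoff = nucleophile_strong_cutoff,
         nucleophile_marginal_cutoff = nucleophile_marginal_cutoff),
    class = "reactivity_config"
  )
}

check_frontier <- function(homo, lumo) {
  if (!all(is.finite(homo)) || !all(is.finite(lumo))) {
    stop("HOMO and LUMO must be finite", call. = FALSE)
  }
}

#' Electronegativity from frontier orbital energies
#'
#' chi = -(eH + eL)/2, i.e. minus the chemical potential mu = (eH + eL)/2.
#' The magnitude convention (positive chi for bound frontier orbitals) is
#' the one reactivity tables report.
#'
#' @param homo,lumo Frontier orbital energies of the neutral (eV).
#' @return Electronegativity chi (eV).
#' @seealso [chemical_potential()]
#' @export
electronegativity <- function(homo, lumo) {
  check_frontier(homo, lumo)
  -(homo + lumo) / 2
}

#' Chemical potential mu = (eH + eL)/2 = -chi
#'
#' @inheritParams electronegativity
#' @return Chemical potential (eV), negative for bound systems.
#' @export
chemical_potential <- function(homo, lumo) {
  -electronegativity(homo, lumo)
}

#' Global hardness as the full HOMO-LUMO gap
#'
#' eta = eL - eH, with no 1/2 factor: this is the convention under which
#' the published hardness column coincides with the printed H-L gap.
#'
#' @inheritParams electronegativity
#' @return Hardness eta (eV). If `lumo <= homo` the (non-positive) value is
#'   still returned, with a warning, so that malformed records surface in
#'   reports rather than vanish.
#' @export
hardness <- function(homo, lumo) {
  check_frontier(homo, lumo)
  if (lumo <= homo) {
    warning(sprintf("LUMO (%.4f) does not lie above HOMO (%.4f); hardness is not positive",
                    lumo, homo), call. = FALSE)
  }
  lumo - homo
}

#' Global softness S = 1/eta
#'
#' @param eta Hardness (eV), non-zero.
#' @return Softness (1/eV).
#' @export
softness <- function(eta) {
  if (eta == 0) stop("softness is undefined at zero hardness", call. = FALSE)
  1 / eta
}

#' Electrophilicity index
#'
#' omega = chi^2 / (2 eta) = (eH + eL)^2 / (8 (eL - eH)), the
#' Parr-style compromise between the drive to acquire electron density and
#' the resistance to exchanging it. The `denominator = "4eta"` variant,
#' (eH + eL)^2 / (4 eta) = chi^2/eta, is twice the default and is retained
#' only for auditing alternative conventions; the default reproduces the
#' shipped reference tables.
#'
#' @inheritParams electronegativity
#' @param denominator `"8eta"` (default, omega = chi^2/(2 eta)) or
#'   `"4eta"` (omega = chi^2/eta).
#' @return Electrophilicity omega (eV), non-negative.
#' @export
electrophilicity <- function(homo, lumo, denominator = c("8eta", "4eta")) {
  denominator <- match.arg(denominator)
  check_frontier(homo, lumo)
  gap <- lumo - homo
  if (gap == 0) stop("electrophilicity is undefined at zero gap", call. = FALSE)
  w <- (homo + lumo)^2 / (8 * gap)
  if (denominator == "4eta") w <- 2 * w
  w
}

#' Electrodonating and electroaccepting powers and net electrophilicity
#'
#' omega^- = (3 eH + eL)^2 / (16 eta) (propensity to donate charge),
#' omega^+ = (eH + 3 eL)^2 / (16 eta) (propensity to accept charge),
#' and their sum, the net electrophilicity Delta omega^+-. The difference
#' omega^- - omega^+ equals chi identically.
#'
#' @inheritParams electronegativity
#' @return Named list with `omega_minus`, `omega_plus`,
#'   `net_electrophilicity` (all eV).
#' @export
charge_transfer_powers <- function(homo, lumo) {
  check_frontier(homo, lumo)
  eta <- lumo - homo
  if (eta == 0) {
    stop("charge-transfer powers are undefined at zero gap", call. = FALSE)
  }
  wm <- (3 * homo + lumo)^2 / (16 * eta)
  wp <- (homo + 3 * lumo)^2 / (16 * eta)
  list(omega_minus = wm, omega_plus = wp, net_electrophilicity = wm + wp)
}

#' Nucleophilicity index on the TCE scale
#'
#' N = eH(molecule) - eH(TCE), the HOMO energy shifted so that
#' tetracyanoethylene, a very poor nucleophile, sits at the origin.
#'
#' @param homo HOMO energy of the neutral molecule (eV).
#' @param config A [reactivity_config()] supplying the TCE reference.
#' @return Nucleophilicity N (eV).
#' @export
nucleophilicity <- function(homo, config = reactivity_config()) {
  if (!is.finite(homo)) stop("HOMO must be finite", call. = FALSE)
  homo - config$tce_homo_reference
}

#' Classify a molecule on the electrophilicity scale
#'
#' Strong above 1.5 eV, marginal below 0.8 eV, moderate between. Values
#' landing exactly on a cutoff are assigned to the moderate band.
#'
#' @param omega Electrophilicity (eV), non-negative.
#' @param config A [reactivity_config()].
#' @return `"strong"`, `"moderate"` or `"marginal"` (vectorised).
#' @export
classify_electrophile <- function(omega, config = reactivity_config()) {
  stopifnot(all(omega >= 0))
  ifelse(omega > config$electrophile_strong_cutoff, "strong",
         ifelse(omega >= config$electrophile_marginal_cutoff, "moderate",
                "marginal"))
}

#' Classify a molecule on the nucleophilicity scale
#'
#' Strong above 3.0 eV, marginal at or below 2.0 eV, moderate between
#' (an exact 3.0 is moderate: boundary ties resolve toward the middle
#' band).
#'
#' @param nu Nucleophilicity (eV).
#' @param config A [reactivity_config()].
#' @return `"strong"`, `"moderate"` or `"marginal"` (vectorised).
#' @export
classify_nucleophile <- function(nu, config = reactivity_config()) {
  ifelse(nu > config$nucleophile_strong_cutoff, "strong",
         ifelse(nu > config$nucleophile_marginal_cutoff, "moderate",
                "marginal"))
}

#' Full global descriptor set for one molecule
#'
#' Assembles chi, eta, omega, S, N, omega^-, omega^+ and Delta omega^+-
#' from the neutral species' frontier orbitals, plus the scale bands.
#'
#' @param mol A [molecule_energetics()] whose neutral species has HOMO and
#'   LUMO set.
#' @param config A [reactivity_config()].
#' @return An object of class `global_descriptor_set` (a named list).
#' @export
global_descriptor_set <- function(mol, config = reactivity_config()) {
  stopifnot(inherits(mol, "molecule_energetics"))
  h <- mol$neutral$homo
  l <- mol$neutral$lumo
  if (is.na(h) || is.na(l)) {
    stop(sprintf("molecule '%s': neutral HOMO/LUMO required for global descriptors",
                 mol$molecule_id), call. = FALSE)
  }
  chi <- electronegativity(h, l)
  eta <- hardness(h, l)
  ctp <- charge_transfer_powers(h, l)
  omega <- electrophilicity(h, l)
  nu <- nucleophilicity(h, config)
  structure(
    list(molecule_id = mol$molecule_id,
         chi = chi, eta = eta, softness = softness(eta), omega = omega,
         nu = nu,
         omega_minus = ctp$omega_minus, omega_plus = ctp$omega_plus,
         net_electrophilicity = ctp$net_electrophilicity,
         electrophile_band = classify_electrophile(omega, config),
         nucleophile_band = classify_nucleophile(nu, config)),
    class = "global_descriptor_set"
  )
}

#' Global descriptor table for a set of molecules
#'
#' One row per molecule, ordered by molecule id, with the eight descriptors
#' in the conventional column order (chi, eta, omega, S, N, omega^-,
#' omega^+, net) plus the scale bands.
#'
#' @param triads List of [molecule_energetics()] (e.g. from
#'   [read_energetics_table()]).
#' @param config A [reactivity_config()].
#' @return A data frame.
#' @export
global_descriptor_table <- function(triads, config = reactivity_config()) {
  if (length(triads) == 0L) {
    return(data.frame(molecule_id = character(), chi = numeric(),
                      eta = numeric(), omega = numeric(), softness = numeric(),
                      nu = numeric(), omega_minus = numeric(),
                      omega_plus = numeric(), net_electrophilicity = numeric(),
                      electrophile_band = character(),
                      nucleophile_band = character(),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(triads, function(tr) {
    g <- global_descriptor_set(tr, config)
    data.frame(molecule_id = g$molecule_id, chi = g$chi, eta = g$eta,
               omega = g$omega, softness = g$softness, nu = g$nu,
               omega_minus = g$omega_minus, omega_plus = g$omega_plus,
               net_electrophilicity = g$net_electrophilicity,
               electrophile_band = g$electrophile_band,
               nucleophile_band = g$nucleophile_band,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$molecule_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
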