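# Shared fixture access and small builders used across test files.

veraguamide_triads <- function() {
  read_energetics_table(cdft_example("veraguamides_mn12sx_h2o_energetics.csv"))
}

published_global <- function() {
  utils::read.csv(cdft_example("veraguamides_global_published.csv"),
                  check.names = FALSE, strip.white = TRUE)
}

published_kid <- function() {
  utils::read.csv(cdft_example("veraguamides_kid_published.csv"),
                  check.names = FALSE, strip.white = TRUE)
}

benchmark_cells <- function() {
  read_benchmark_table(cdft_example("gkd_benchmark_solvents.csv"),
                       n_molecules = 7L)
}

# A complete triad with every input settable; defaults are a perfectly
# Koopmans-compliant molecule (eH = -I, eL = -A, SOMO = LUMO).
make_triad <- function(id = "toy", I = 6, A = 1,
                       homo = -I, lumo = -A, somo = lumo,
                       e_neutral = 0, e_cation = I, e_anion = -A) {
  molecule_energetics(
    id, "TEST", solvent_spec("none", 1),
    neutral = species_record(id, 0L, 1L, total_energy = e_neutral,
                             homo = homo, lumo = lumo),
    cation = species_record(id, 1L, 2L, total_energy = e_cation),
    anion = species_record(id, -1L, 2L, total_energy = e_anion, somo = somo)
  )
}

descriptor_columns <- c("chi", "eta", "omega", "softness", "nu",
                        "omega_minus", "omega_plus", "net_electrophilicity")
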