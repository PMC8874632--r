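#!/usr/bin/env Rscript
# Internal-consistency audit of the published KID indices: J(HL) as the
# Euclidean norm of J(I), J(A), and Delta(SL) recomputed from the printed
# SOMO/LUMO energies.
library(cdftpept)

dir.create("results", showWarnings = FALSE)

triads <- read_energetics_table(
  cdft_example("veraguamides_mn12sx_h2o_energetics.csv")
)
pub <- read.csv(cdft_example("veraguamides_kid_published.csv"),
                strip.white = TRUE)

audit <- data.frame(
  molecule_id = pub$molecule_id,
  j_hl_published = pub$j_hl,
  j_hl_from_ji_ja = j_hl(pub$j_i, pub$j_a),
  delta_sl_published = pub$delta_sl,
  delta_sl_from_orbitals = vapply(pub$molecule_id,
                                  function(id) delta_sl(triads[[id]]),
                                  numeric(1))
)
audit$j_hl_consistent <- abs(audit$j_hl_published - audit$j_hl_from_ji_ja) <= 0.0015
audit$delta_sl_consistent <-
  abs(audit$delta_sl_published - audit$delta_sl_from_orbitals) <= 0.0015

write.csv(audit, "results/kid_consistency.csv", row.names = FALSE)
print(audit, digits = 3)
cat(sprintf("\nJ(HL) consistent for %d/7 molecules; Delta(SL) for %d/7\n",
            sum(audit$j_hl_consistent), sum(audit$delta_sl_consistent)))
cat("Delta(SL) inconsistencies (expected: A and F carry a print discrepancy):",
    paste(audit$molecule_id[!audit$delta_sl_consistent], collapse = ", "), "\n")
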