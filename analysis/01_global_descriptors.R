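#!/usr/bin/env Rscript
# Global reactivity descriptors of the Veraguamides A-G from the shipped
# MN12SX/Def2TZVP (SMD water) frontier orbital energies, compared against
# the published descriptor table.
library(cdftpept)

dir.create("results", showWarnings = FALSE)

triads <- read_energetics_table(
  cdft_example("veraguamides_mn12sx_h2o_energetics.csv")
)
desc <- global_descriptor_table(triads, reactivity_config())

pub <- read.csv(cdft_example("veraguamides_global_published.csv"),
                strip.white = TRUE)
num <- c("chi", "eta", "omega", "softness", "nu",
         "omega_minus", "omega_plus", "net_electrophilicity")
max_dev <- max(abs(as.matrix(desc[num]) - as.matrix(pub[num])))

write.csv(desc, "results/global_descriptors.csv", row.names = FALSE)

cat("Global descriptors for", nrow(desc), "molecules\n")
print(desc[, c("molecule_id", num)], digits = 4)
cat(sprintf("\nMax |recomputed - published| over all %d values: %.4f eV\n",
            length(num) * nrow(desc), max_dev))
cat("Electrophile bands:", paste(unique(desc$electrophile_band),
                                 collapse = ", "), "\n")
cat("Marginal nucleophiles:",
    paste(desc$molecule_id[desc$nucleophile_band == "marginal"],
          collapse = ", "), "\n")
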