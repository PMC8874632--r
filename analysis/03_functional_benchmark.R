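#!/usr/bin/env Rscript
# Ranking of ten density functionals by mean global KID descriptor across
# twelve solvents, from the shipped benchmark matrix.
library(cdftpept)

dir.create("results", showWarnings = FALSE)

cells <- read_benchmark_table(cdft_example("gkd_benchmark_solvents.csv"),
                              n_molecules = 7L)
solvents <- unique(cells$solvent_name)
ranking <- do.call(rbind, lapply(solvents, function(sv) {
  r <- rank_functionals(cells, sv)
  data.frame(solvent = sv,
             best = r[1L], second = r[2L],
             best_mean_gkd = min(cells$mean_gkd[cells$solvent_name == sv]))
}))

write.csv(ranking, "results/functional_ranking.csv", row.names = FALSE)
print(ranking)
cat("\nMN12SX is best in:",
    paste(ranking$solvent[ranking$best == "MN12SX"], collapse = ", "), "\n")
cat("Gas-phase leaders:",
    paste(rank_functionals(cells, "Gas")[1:2], collapse = ", "), "\n")
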