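#!/usr/bin/env Rscript
# Generate the synthetic multi-environment hybrid trial used by the rest
# of the analysis: two disjoint parental pools (20 B-lines x 13 R-lines),
# the complete factorial of 260 hybrids plus the 33 parental inbreds,
# grain yield in 4 environments, with the variance composition typical of
# such trials (environment ~50%, GCA/SCA/GxE terms a few percent each).
# Writes markers, pedigree, phenotypes, and the ground-truth effect
# layers under results/simulated_study/.
#
# Usage: Rscript analysis/01_simulate.R [seed]

library(hybridGP)

seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1

cfg <- simulation_config(seed = seed)
study <- simulate_study(cfg)
print(study)

paths <- write_study_csv(study, "results/simulated_study")
cat("wrote:\n"); cat(paste(" ", paths, collapse = "\n"), "\n")

# realized variance composition of the generated trial (hybrid records)
hyb <- study$pheno$genotype_class == "hybrid"
env_var <- var(study$truth$E[match(study$pheno$environment_id[hyb],
                                   names(study$truth$E))])
lay <- vapply(study$truth$layers, function(l) var(l[hyb]), numeric(1))
res <- var(study$truth$residual[hyb])
realized <- c(E = env_var, lay, R = res)
cat("\nrealized variance shares (%) on hybrid records:\n")
print(round(100 * realized / sum(realized), 1))
cat("configured shares (%):\n")
print(100 * cfg$shares)
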