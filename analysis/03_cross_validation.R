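#!/usr/bin/env Rscript
# Benchmark the models under the three cross-validation schemes on the
# simulated trial: CV2 (incomplete trials; record-level folds), CV1
# (untested hybrids; genotype-level folds), CV0 (unobserved environment;
# leave-one-environment-out), each with and without augmenting the
# calibration sets with the parental inbred phenotypes. Reports the mean
# within-environment predictive ability (Pearson correlation) and its SD
# across replicates, and writes results/predictive_ability.csv.
#
# Replicates and folds are scaled to desk size (2 x 2); increase `reps`
# and `k` below for smoother estimates.
#
# Usage: Rscript analysis/03_cross_validation.R [seed]

library(hybridGP)

seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1

dir <- "results/simulated_study"
if (!file.exists(file.path(dir, "markers.csv")))
  stop("run analysis/01_simulate.R first")

markers <- read_marker_matrix(file.path(dir, "markers.csv"), "delimited")
ped <- pedigree_table(read.csv(file.path(dir, "pedigree.csv")))
pheno <- phenotype_table(read.csv(file.path(dir, "phenotypes.csv")))
rec <- pheno[pheno$genotype_class == "hybrid", ]
inb <- pheno[pheno$genotype_class == "inbred", ]

sp <- model_spec(iterations = 1500, burn_in = 500, thin = 2,
                 standardize = TRUE)
reps <- 2; k <- 2

runs <- list()
for (model in c("M1", "M3")) {
  for (scheme in c("CV2", "CV1", "CV0")) {
    for (augment in c(FALSE, TRUE)) {
      res <- run_cv(rec, ped, markers, scheme, model, sp,
                    augment = augment, inbred_pheno = inb,
                    k = k, reps = reps, seed = seed, center = TRUE)
      print(res)
      runs[[length(runs) + 1]] <- res
    }
  }
}

tab <- do.call(cv_result_table, runs)
dir.create("results", showWarnings = FALSE)
write.csv(tab, "results/predictive_ability.csv", row.names = FALSE)
cat("\nwrote results/predictive_ability.csv\n")

cat("\nscheme x model means across environments:\n")
print(aggregate(mean ~ scheme + model + augment, tab, mean), digits = 3)
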