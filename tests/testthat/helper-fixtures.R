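# Shared fixtures, all generated in code.

# Desk-scale simulation config: 6 B-lines x 5 R-lines, 18 hybrids, 2 envs.
tiny_config <- function(seed = 1, ...) {
  simulation_config(n_b_lines = 6, n_r_lines = 5, n_hybrids = 18,
                    n_loci = 300, n_env = 2, seed = seed, ...)
}

# Pedigree with n_hyb hybrids over disjoint B/R pools; parent pairs may
# repeat when n_hyb exceeds the factorial, ids stay unique.
make_pedigree <- function(n_b, n_r, n_hyb, inbreds = FALSE) {
  b <- sprintf("B%02d", seq_len(n_b))
  r <- sprintf("R%02d", seq_len(n_r))
  ped <- data.frame(genotype_id = sprintf("H%03d", seq_len(n_hyb)),
                    p1_id = b[(seq_len(n_hyb) - 1) %% n_b + 1],
                    p2_id = r[(seq_len(n_hyb) - 1) %% n_r + 1],
                    genotype_class = "hybrid", stringsAsFactors = FALSE)
  if (inbreds) {
    ids <- c(b, r)
    ped <- rbind(ped, data.frame(genotype_id = ids, p1_id = ids, p2_id = ids,
                                 genotype_class = "inbred",
                                 stringsAsFactors = FALSE))
  }
  pedigree_table(ped)
}

# Long phenotype table over every genotype x environment cell.
make_records <- function(ped, n_env, seed = 1) {
  set.seed(seed)
  envs <- sprintf("E%d", seq_len(n_env))
  phenotype_table(data.frame(
    genotype_id = rep(ped$genotype_id, times = n_env),
    environment_id = rep(envs, each = nrow(ped)),
    value = rnorm(nrow(ped) * n_env, 3000, 500),
    genotype_class = rep(ped$genotype_class, times = n_env),
    stringsAsFactors = FALSE))
}

# Random inbred-coded marker matrix ({0, 2} entries).
random_markers <- function(n_lines, n_loci, seed = 1, prefix = "L") {
  set.seed(seed)
  x <- matrix(2 * rbinom(n_lines * n_loci, 1, 0.6), n_lines,
              dimnames = list(sprintf("%s%02d", prefix, seq_len(n_lines)),
                              sprintf("s%03d", seq_len(n_loci))))
  marker_matrix(x)
}

random_psd <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- matrix(rnorm(n * n), n)
  crossprod(a) / n
}

# kernel_set wrapper around explicit record-level matrices (for fitter
# tests that need full control of the covariance).
manual_kernel_set <- function(K_list, model = "M1") {
  structure(list(model = model, labels = names(K_list), K = K_list,
                 n_records = nrow(K_list[[1]])), class = "kernel_set")
}
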