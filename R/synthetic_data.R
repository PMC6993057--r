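#' Configuration for the synthetic multi-environment hybrid trial
#'
#' The defaults mirror a realistic two-pool hybrid trial: 20 seed-parent
#' (B) lines crossed with 13 pollinator (R) lines giving the complete
#' factorial of 260 distinct hybrids, plus the 33 parental inbreds
#' themselves, all observed for grain yield (kg/ha) in 4 environments. Variance shares follow the
#' magnitudes typical of such trials: environment about half of the total
#' variability, small parent-1 GCA, moderate parent-2 GCA, SCA and each
#' genotype-by-environment term around 5–7%, the rest residual.
#'
#' @param n_b_lines,n_r_lines Sizes of the two disjoint parental pools.
#' @param n_hybrids Number of crosses sampled from the B x R grid.
#' @param n_loci Number of biallelic SNP loci (default 5000; a desk-scale
#'   stand-in for a dense GBS panel).
#' @param maf_range Range the per-locus minor allele frequency is drawn
#'   from (uniform), default `c(0.05, 0.5)`.
#' @param n_env Number of environments.
#' @param grand_mean Trait grand mean, kg/ha.
#' @param total_variance Total phenotypic variance (kg/ha)^2.
#' @param shares Named variance shares for
#'   `E`, `G_P1`, `G_P2`, `G_P1xP2`, `G_P1xE`, `G_P2xE`, `G_P1xP2xE`, `R`;
#'   non-negative, summing to 1.
#' @param include_inbreds Also generate phenotypes for the parental
#'   inbreds (as self-crosses)? Default `TRUE`.
#' @param seed Integer seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_b_lines = 20, n_r_lines = 13,
                              n_hybrids = 260, n_loci = 5000,
                              maf_range = c(0.05, 0.5), n_env = 4,
                              grand_mean = 3000, total_variance = 1e6,
                              shares = c(E = 0.50, G_P1 = 0.02, G_P2 = 0.06,
                                         G_P1xP2 = 0.06, G_P1xE = 0.06,
                                         G_P2xE = 0.06, G_P1xP2xE = 0.06,
                                         R = 0.18),
                              include_inbreds = TRUE, seed = NULL) {
  need <- c("E", "G_P1", "G_P2", "G_P1xP2", "G_P1xE", "G_P2xE",
            "G_P1xP2xE", "R")
  if (!all(need %in% names(shares)))
    stop("shares needs names: ", paste(need, collapse = ", "))
  shares <- shares[need]
  if (any(shares < 0) || abs(sum(shares) - 1) > 1e-9)
    stop("shares must be non-negative and sum to 1")
  if (n_hybrids > n_b_lines * n_r_lines)
    stop("n_hybrids exceeds the B x R grid")
  if (maf_range[1] < 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop("maf_range must lie within [0, 0.5]")
  structure(list(n_b_lines = n_b_lines, n_r_lines = n_r_lines,
                 n_hybrids = n_hybrids, n_loci = n_loci,
                 maf_range = maf_range, n_env = n_env,
                 grand_mean = grand_mean, total_variance = total_variance,
                 shares = shares, include_inbreds = include_inbreds,
                 seed = seed), class = "simulation_config")
}

#' Simulate parental inbred marker panels
#'
#' Per locus a minor allele frequency is drawn uniformly from the
#' configured range; each fully inbred line then carries 0 or 2 copies of
#' the major allele (2 with probability `1 - maf`), independently across
#' loci and lines. B-lines and R-lines form disjoint id pools.
#'
#' @param config A [simulation_config()].
#' @return A `marker_matrix` over all `n_b_lines + n_r_lines` parents,
#'   entries in `{0, 2}`.
#' @export
simulate_parents <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  simulate_parents_core(config)
}

simulate_parents_core <- function(config) {
  n_lines <- config$n_b_lines + config$n_r_lines
  maf <- stats::runif(config$n_loci, config$maf_range[1], config$maf_range[2])
  # counts of the MAJOR allele: 2 with probability 1 - maf
  x <- matrix(2 * stats::rbinom(n_lines * config$n_loci, 1,
                                rep(1 - maf, each = n_lines)),
              nrow = n_lines,
              dimnames = list(c(sprintf("B%02d", seq_len(config$n_b_lines)),
                                sprintf("R%02d", seq_len(config$n_r_lines))),
                              sprintf("snp%05d", seq_len(config$n_loci))))
  marker_matrix(x)
}

#' Simulate a complete multi-environment hybrid trial with known truth
#'
#' The generator is the exact probabilistic twin of the most comprehensive
#' fitted model: it builds the parental marker panels, samples hybrids
#' from the B x R grid, assembles the full set of GCA/SCA/interaction
#' kernels over all records via [assemble_kernels()] (column-centered
#' GRMs, each record-level kernel standardized to mean diagonal 1 so that
#' variance shares are on the record scale), and draws every effect layer
#' from its multivariate normal `N(0, C * share * total_variance)` using
#' the kernel eigendecomposition. Environment intercepts and residuals
#' are drawn iid. Phenotypes are the exact sum of the stored layers.
#' Inbred phenotypes, when generated, follow the self-cross rule (the
#' same line in both parental slots).
#'
#' @param config A [simulation_config()].
#' @return A `simulated_study`: `markers` (`marker_matrix`), `ped`
#'   (pedigree table), `pheno` (phenotype table over all records),
#'   `truth` (list: `mu`, `E`, per-term record-level `layers`,
#'   `residual`, `shares`, `total_variance`), and `config`.
#' @export
simulate_study <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  markers <- simulate_parents_core(config)
  markers <- filter_maf(markers, 0.05)
  b_ids <- line_ids(markers)[seq_len(config$n_b_lines)]
  r_ids <- line_ids(markers)[config$n_b_lines + seq_len(config$n_r_lines)]

  grid <- expand.grid(p1 = b_ids, p2 = r_ids, stringsAsFactors = FALSE)
  pick <- sort(sample.int(nrow(grid), config$n_hybrids))
  ped <- data.frame(genotype_id = sprintf("H%03d", seq_len(config$n_hybrids)),
                    p1_id = grid$p1[pick], p2_id = grid$p2[pick],
                    genotype_class = "hybrid", stringsAsFactors = FALSE)
  if (config$include_inbreds) {
    inb <- c(b_ids, r_ids)
    ped <- rbind(ped, data.frame(genotype_id = inb, p1_id = inb, p2_id = inb,
                                 genotype_class = "inbred",
                                 stringsAsFactors = FALSE))
  }
  ped <- pedigree_table(ped)
  envs <- sprintf("E%d", seq_len(config$n_env))
  pheno <- data.frame(
    genotype_id = rep(ped$genotype_id, times = config$n_env),
    environment_id = rep(envs, each = nrow(ped)),
    value = 0,
    genotype_class = rep(ped$genotype_class, times = config$n_env),
    stringsAsFactors = FALSE)
  n <- nrow(pheno)

  g <- build_grm(center_markers(markers))
  ks <- assemble_kernels("M3", pheno, ped, g, g, standardize = TRUE)
  ks <- prepare_kernels(ks)

  tv <- config$total_variance
  sh <- config$shares
  layers <- lapply(ks$labels, function(lab) {
    e <- ks$eig[[lab]]
    as.numeric(e$vectors %*% (stats::rnorm(length(e$values)) *
                                sqrt(e$values * sh[[lab]] * tv)))
  })
  names(layers) <- ks$labels
  E <- stats::rnorm(config$n_env, 0, sqrt(sh[["E"]] * tv))
  names(E) <- envs
  residual <- stats::rnorm(n, 0, sqrt(sh[["R"]] * tv))
  envidx <- match(pheno$environment_id, envs)
  pheno$value <- config$grand_mean + E[envidx] +
    Reduce(`+`, layers) + residual

  structure(list(markers = markers, ped = ped,
                 pheno = phenotype_table(pheno),
                 truth = list(mu = config$grand_mean, E = E, layers = layers,
                              residual = residual, shares = sh,
                              total_variance = tv),
                 config = config),
            class = "simulated_study")
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf(paste0("simulated_study: %d hybrids%s x %d environments, ",
                     "%d loci after MAF filter\n"),
              x$config$n_hybrids,
              if (x$config$include_inbreds)
                sprintf(" + %d inbreds",
                        x$config$n_b_lines + x$config$n_r_lines) else "",
              x$config$n_env, ncol(x$markers$counts)))
  invisible(x)
}

#' Write a simulated study as the canonical CSV inputs
#'
#' Emits the marker table, pedigree, phenotypes and the ground-truth
#' effect layers into a directory, in the formats the ingestion functions
#' read back.
#'
#' @param study A `simulated_study`.
#' @param dir Output directory (created if needed).
#' @return Character vector of the four file paths, invisibly.
#' @export
write_study_csv <- function(study, dir) {
  stopifnot(inherits(study, "simulated_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("markers.csv", "pedigree.csv",
                            "phenotypes.csv", "truth.csv"))
  write_marker_matrix(study$markers, paths[1])
  utils::write.csv(study$ped, paths[2], row.names = FALSE)
  utils::write.csv(study$pheno, paths[3], row.names = FALSE)
  truth <- data.frame(study$pheno[, c("genotype_id", "environment_id")],
                      as.data.frame(study$truth$layers, check.names = FALSE),
                      E = study$truth$E[match(study$pheno$environment_id,
                                              names(study$truth$E))],
                      residual = study$truth$residual)
  utils::write.csv(truth, paths[4], row.names = FALSE)
  invisible(paths)
}
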