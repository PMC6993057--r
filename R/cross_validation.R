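#' Random-record fold assignments (CV2)
#'
#' CV2 mimics an incomplete field trial: phenotype records (not genotypes)
#' are shuffled and split into `k` near-equal folds, independently per
#' replicate. Inbred records, when present in the table, are never
#' assigned to a test fold.
#'
#' @param records Phenotype table.
#' @param k Number of folds (default 5).
#' @param reps Number of replicates (default 50).
#' @param seed Base seed; replicate `r` uses `seed + r`.
#' @return List of `cv_partition` objects: `scheme`, `replicate`, `fold`
#'   (integer per record, `NA` for inbred records), `seed`.
#' @export
partition_cv2 <- function(records, k = 5, reps = 50, seed = 1) {
  records <- phenotype_table(records)
  if (k < 2) stop("need at least 2 folds")
  hyb <- which(records$genotype_class == "hybrid")
  if (length(hyb) < k) stop("fewer hybrid records than folds")
  lapply(seq_len(reps), function(r) {
    set.seed(seed + r)
    perm <- sample(hyb)
    fold <- rep(NA_integer_, nrow(records))
    fold[perm] <- rep(seq_len(k), times = fold_sizes(length(hyb), k))
    structure(list(scheme = "CV2", replicate = r, fold = fold,
                   seed = seed + r), class = "cv_partition")
  })
}

#' Genotype-level fold assignments (CV1)
#'
#' CV1 predicts untested genotypes: all phenotype records of the same
#' hybrid genotype share a fold, so a test genotype has no record of its
#' own in training.
#'
#' @inheritParams partition_cv2
#' @return List of `cv_partition` objects as in [partition_cv2()].
#' @export
partition_cv1 <- function(records, k = 5, reps = 50, seed = 1) {
  records <- phenotype_table(records)
  if (k < 2) stop("need at least 2 folds")
  hyb <- records$genotype_class == "hybrid"
  geno <- unique(records$genotype_id[hyb])
  if (length(geno) < k) stop("fewer hybrid genotypes than folds")
  lapply(seq_len(reps), function(r) {
    set.seed(seed + r)
    perm <- sample(geno)
    gfold <- stats::setNames(rep(seq_len(k), times = fold_sizes(length(geno), k)),
                             perm)
    fold <- rep(NA_integer_, nrow(records))
    fold[hyb] <- gfold[records$genotype_id[hyb]]
    structure(list(scheme = "CV1", replicate = r, fold = fold,
                   seed = seed + r), class = "cv_partition")
  })
}

# near-equal fold sizes; remainder spread one-per-fold over the first folds
fold_sizes <- function(n, k) {
  base <- n %/% k
  rem <- n %% k
  base + as.integer(seq_len(k) <= rem)
}

#' Leave-one-environment-out partitions (CV0)
#'
#' CV0 predicts performance in an unobserved environment: each partition
#' holds out every hybrid record of one environment; calibration excludes
#' all records (hybrid and inbred) from that environment.
#'
#' @param records Phenotype table with at least two environments.
#' @return List of `cv_partition` objects with a `test_env` field; no
#'   random element, so no replicates.
#' @export
partition_cv0 <- function(records) {
  records <- phenotype_table(records)
  envs <- unique(records$environment_id)
  if (length(envs) < 2L) stop("CV0 needs at least two environments")
  lapply(envs, function(e)
    structure(list(scheme = "CV0", replicate = 1L, test_env = e,
                   fold = NULL, seed = NA_integer_), class = "cv_partition"))
}

#' Augment a calibration set with parental inbred phenotypes
#'
#' Inbred phenotype records are appended to the training table, modeled as
#' self-crosses: the pedigree gains rows with the same line in both
#' parental slots, so kernel assembly places the inbred's own marker row
#' in both parent positions. Inbreds never enter test sets.
#'
#' @param training Hybrid phenotype table.
#' @param inbred_pheno Inbred phenotype table (`genotype_class` is forced
#'   to `"inbred"`).
#' @param ped Pedigree table for the hybrids; self-rows for inbreds are
#'   added if absent.
#' @param markers Optional `marker_matrix`; if given, every inbred must
#'   have a marker row.
#' @return List with `pheno` (training + inbred records) and `ped`
#'   (with inbred self-rows).
#' @export
augment_with_inbreds <- function(training, inbred_pheno, ped, markers = NULL) {
  training <- phenotype_table(training)
  ped <- pedigree_table(ped)
  if (is.null(inbred_pheno) || nrow(inbred_pheno) == 0L)
    return(list(pheno = training, ped = ped))
  inbred_pheno <- phenotype_table(inbred_pheno)
  inbred_pheno$genotype_class <- "inbred"
  ids <- unique(inbred_pheno$genotype_id)
  if (!is.null(markers)) {
    miss <- setdiff(ids, line_ids(markers))
    if (length(miss) > 0L)
      stop("inbred(s) without marker data: ", paste(miss, collapse = ", "))
  }
  new_ids <- setdiff(ids, ped$genotype_id)
  if (length(new_ids) > 0L)
    ped <- rbind(ped, data.frame(genotype_id = new_ids, p1_id = new_ids,
                                 p2_id = new_ids, genotype_class = "inbred",
                                 stringsAsFactors = FALSE))
  list(pheno = rbind(training, inbred_pheno), ped = pedigree_table(ped))
}

#' Run a cross-validation scheme for one model
#'
#' Orchestrates the full scheme: assembles the record-level kernels once
#' (eigendecomposed once and reused across folds and replicates), then for
#' each fold masks the test responses, refits the model with the masked
#' records predicted by data augmentation, integrates all folds'
#' predictions into a single vector per replicate, and computes the
#' within-environment Pearson correlation between predicted and observed
#' hybrid values. CV2/CV1 correlations are averaged over replicates; CV0
#' yields a single value per environment.
#'
#' @param records Hybrid phenotype table (complete cases).
#' @param ped Pedigree table covering all genotypes.
#' @param markers Imputed, MAF-filtered `marker_matrix` covering every
#'   parent line (both pools).
#' @param scheme `"CV2"`, `"CV1"` or `"CV0"`.
#' @param model `"M1"`, `"M2"` or `"M3"`.
#' @param spec A [model_spec()] for the per-fold fits; replicate `r`,
#'   fold `f` uses seed `seed + 1000 * r + f`.
#' @param augment Add inbred phenotypes to every calibration set?
#' @param inbred_pheno Inbred phenotype table (required when
#'   `augment = TRUE`).
#' @param k,reps Folds and replicates for CV2/CV1 (defaults 5 and 50).
#' @param seed Base seed for partitioning and fits.
#' @param center Column-center markers before the GRM (see [build_grm()]).
#' @return A `cv_result`: `per_replicate` (replicates x environments
#'   correlation matrix), `predictions` (replicates x hybrid-records
#'   integrated prediction matrix, in `records` order), `mean` and `sd`
#'   per environment (`sd` `NA` for CV0), plus the run configuration.
#' @export
run_cv <- function(records, ped, markers,
                   scheme = c("CV2", "CV1", "CV0"),
                   model = c("M3", "M1", "M2"),
                   spec = model_spec(), augment = FALSE,
                   inbred_pheno = NULL, k = 5, reps = 50, seed = 1,
                   center = FALSE) {
  scheme <- match.arg(scheme)
  model <- match.arg(model)
  records <- phenotype_table(records)
  if (any(records$genotype_class != "hybrid"))
    stop("records must contain hybrid phenotypes only; pass inbreds via inbred_pheno")
  if (augment && is.null(inbred_pheno))
    stop("augment = TRUE needs inbred_pheno")
  aug <- if (augment)
    augment_with_inbreds(records, inbred_pheno, ped, markers)
  else list(pheno = records, ped = pedigree_table(ped))
  recs <- aug$pheno
  ped_all <- aug$ped
  g <- build_grm(markers, standardize = FALSE)
  if (center) g <- build_grm(center_markers(markers), standardize = FALSE)
  ks <- assemble_kernels(model, recs, ped_all, g, g,
                         standardize = spec$standardize)
  ks <- prepare_kernels(ks)
  env <- build_incidence(recs, ped_all, "environment")
  is_hyb <- recs$genotype_class == "hybrid"
  hyb_env <- recs$environment_id[is_hyb]
  envs <- colnames(env)

  parts <- switch(scheme,
    CV2 = partition_cv2(recs, k, reps, seed),
    CV1 = partition_cv1(recs, k, reps, seed),
    CV0 = partition_cv0(recs))

  fit_one <- function(mask_idx, fit_seed) {
    yy <- recs$value
    yy[mask_idx] <- NA
    sp <- spec
    sp$seed <- fit_seed
    sp$standardize <- FALSE  # already applied at assembly
    fit_gibbs(yy, env, ks, sp)
  }

  if (scheme == "CV0") {
    per_rep <- matrix(NA_real_, 1L, length(envs), dimnames = list(NULL, envs))
    predictions <- matrix(NA_real_, 1L, sum(is_hyb))
    for (p in parts) {
      mask <- which(recs$environment_id == p$test_env)  # hybrids + inbreds
      fit <- fit_one(mask, seed + match(p$test_env, envs))
      test_h <- which(recs$environment_id == p$test_env & is_hyb)
      predictions[1L, hyb_env == p$test_env] <- fit$yhat[test_h]
      pa <- pearson_within_env(fit$yhat[test_h], recs$value[test_h],
                               recs$environment_id[test_h])
      per_rep[1L, p$test_env] <- pa$value[pa$environment == p$test_env]
    }
    res_mean <- per_rep[1L, ]
    res_sd <- stats::setNames(rep(NA_real_, length(envs)), envs)
  } else {
    per_rep <- matrix(NA_real_, reps, length(envs), dimnames = list(NULL, envs))
    predictions <- matrix(NA_real_, reps, sum(is_hyb))
    for (p in parts) {
      preds <- rep(NA_real_, nrow(recs))
      for (f in seq_len(k)) {
        mask <- which(!is.na(p$fold) & p$fold == f)
        fit <- fit_one(mask, seed + 1000L * p$replicate + f)
        preds[mask] <- fit$yhat[mask]
      }
      predictions[p$replicate, ] <- preds[is_hyb]
      pa <- pearson_within_env(preds[is_hyb], recs$value[is_hyb], hyb_env)
      per_rep[p$replicate, pa$environment] <- pa$value
    }
    res_mean <- colMeans(per_rep, na.rm = TRUE)
    res_sd <- apply(per_rep, 2, stats::sd, na.rm = TRUE)
  }
  structure(list(scheme = scheme, model = model, augment = augment,
                 platform_tag = markers$platform_tag,
                 environments = envs, per_replicate = per_rep,
                 predictions = predictions,
                 mean = res_mean, sd = res_sd,
                 k = if (scheme == "CV0") NA_integer_ else k,
                 reps = if (scheme == "CV0") 1L else reps,
                 seed = seed), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result %s / %s%s: mean predictive ability per environment\n",
              x$scheme, x$model, if (x$augment) " (+inbreds)" else ""))
  print(round(rbind(mean = x$mean, sd = x$sd), 3))
  invisible(x)
}

#' Column-center a marker matrix
#'
#' Subtracts the per-locus mean allele count, the VanRaden-style centering
#' option for relationship matrices.
#'
#' @param m An imputed `marker_matrix`.
#' @return A `marker_matrix`-like object with centered counts (entries no
#'   longer restricted to \[0, 2\]).
#' @export
center_markers <- function(m) {
  stopifnot(inherits(m, "marker_matrix"))
  if (anyNA(m$counts)) stop("impute before centering")
  x <- sweep(m$counts, 2L, colMeans(m$counts))
  structure(list(counts = x, platform_tag = m$platform_tag),
            class = "marker_matrix")
}

#' Tidy cross-validation results in tabular layout
#'
#' @param ... One or more `cv_result` objects.
#' @return Data frame with columns `scheme`, `platform`, `augment`,
#'   `model`, `environment`, `mean`, `sd`.
#' @export
cv_result_table <- function(...) {
  rs <- list(...)
  do.call(rbind, lapply(rs, function(x)
    data.frame(scheme = x$scheme, platform = x$platform_tag,
               augment = x$augment, model = x$model,
               environment = x$environments,
               mean = as.numeric(x$mean), sd = as.numeric(x$sd),
               row.names = NULL)))
}
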