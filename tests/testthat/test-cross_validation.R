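test_that("CV2 folds are near-equal, deterministic, and cover every hybrid record", {
  ped <- make_pedigree(20, 13, 276)
  rec <- make_records(ped, 4)  # 1104 hybrid records
  parts <- partition_cv2(rec, k = 5, reps = 3, seed = 10)
  sizes <- table(parts[[1]]$fold)
  expect_true(all(sizes %in% c(220, 221)))
  # same seed twice: identical partitions
  again <- partition_cv2(rec, k = 5, reps = 3, seed = 10)
  expect_identical(lapply(parts, `[[`, "fold"), lapply(again, `[[`, "fold"))
  # coverage: every record in exactly one fold, every replicate
  for (p in parts) {
    expect_true(all(!is.na(p$fold)))
    expect_equal(sum(table(p$fold)), 1104L)
  }
  expect_error(partition_cv2(rec, k = 1), "folds")
})

test_that("CV2 never assigns inbred records to test folds", {
  ped <- make_pedigree(4, 3, 8, inbreds = TRUE)
  rec <- make_records(ped, 2)
  p <- partition_cv2(rec, k = 2, reps = 1, seed = 1)[[1]]
  expect_true(all(is.na(p$fold[rec$genotype_class == "inbred"])))
  expect_true(all(!is.na(p$fold[rec$genotype_class == "hybrid"])))
})

test_that("CV1 keeps all records of a genotype in one fold", {
  ped <- make_pedigree(20, 13, 276)
  rec <- make_records(ped, 4)
  parts <- partition_cv1(rec, k = 5, reps = 5, seed = 3)
  for (p in parts) {
    by_geno <- tapply(p$fold, rec$genotype_id, function(f) length(unique(f)))
    expect_true(all(by_geno == 1))
  }
  # genotype group sizes are near-equal: 276 / 5 -> {55, 56}
  gfold <- tapply(parts[[1]]$fold, rec$genotype_id, unique)
  gsizes <- table(gfold)
  expect_true(all(gsizes %in% c(55, 56)))
  # per-fold record count = genotype group size x J on complete data
  expect_equal(as.vector(table(parts[[1]]$fold)), as.vector(gsizes) * 4L)
})

test_that("CV0 enumerates environments with disjoint train/test", {
  ped <- make_pedigree(5, 4, 12, inbreds = TRUE)
  rec <- make_records(ped, 4)
  parts <- partition_cv0(rec)
  expect_length(parts, 4L)
  for (p in parts) {
    test_rec <- rec$environment_id == p$test_env
    expect_equal(sum(test_rec) + sum(!test_rec), nrow(rec))
    expect_false(any(rec$environment_id[!test_rec] == p$test_env))
  }
  one_env <- rec[rec$environment_id == "E1", ]
  expect_error(partition_cv0(one_env), "two environments")
})

test_that("inbred augmentation appends self-cross records", {
  ped <- make_pedigree(20, 13, 276)
  rec <- make_records(ped, 4)
  inb_ids <- c(sprintf("B%02d", 1:20), sprintf("R%02d", 1:13))
  inb <- data.frame(genotype_id = rep(inb_ids, 4),
                    environment_id = rep(sprintf("E%d", 1:4), each = 33),
                    value = rnorm(132, 1500, 300), genotype_class = "inbred")
  aug <- augment_with_inbreds(rec, inb, ped)
  expect_equal(nrow(aug$pheno), 1236L)  # (276 + 33) x 4
  self <- aug$ped[aug$ped$genotype_class == "inbred", ]
  expect_true(all(self$p1_id == self$genotype_id & self$p2_id == self$genotype_id))
  # empty inbred table: unchanged
  same <- augment_with_inbreds(rec, NULL, ped)
  expect_identical(same$pheno, rec)
  # missing markers are caught
  mk <- random_markers(5, 10, 1, "B")
  expect_error(augment_with_inbreds(rec, inb, ped, mk), "without marker")
})

test_that("augmented SCA diagonal follows the dual-slot rule", {
  st <- simulate_study(tiny_config(seed = 6))
  g <- build_grm(st$markers)
  ks <- assemble_kernels("M2", st$pheno, st$ped, g, g)
  inb <- which(st$pheno$genotype_class == "inbred")
  for (r in inb[1:5]) {
    line <- st$pheno$genotype_id[r]
    expect_equal(ks$K$G_P1xP2[r, r], g$values[line, line]^2)
  }
})

test_that("run_cv equals a hand-orchestrated fold loop", {
  st <- simulate_study(simulation_config(
    n_b_lines = 5, n_r_lines = 4, n_hybrids = 20, n_loci = 250, n_env = 2,
    seed = 30))
  rec <- st$pheno[st$pheno$genotype_class == "hybrid", ]
  sp <- model_spec(iterations = 600, burn_in = 200, standardize = TRUE)
  got <- run_cv(rec, st$ped, st$markers, "CV2", "M2", sp,
                k = 2, reps = 3, seed = 77, center = TRUE)
  # hand loop with the same seed policy
  g <- build_grm(center_markers(st$markers))
  ks <- prepare_kernels(assemble_kernels("M2", rec, st$ped, g, g,
                                         standardize = TRUE))
  env <- build_incidence(rec, st$ped, "environment")
  want <- matrix(NA_real_, 3, 2, dimnames = list(NULL, c("E1", "E2")))
  for (p in partition_cv2(rec, k = 2, reps = 3, seed = 77)) {
    preds <- rep(NA_real_, nrow(rec))
    for (f in 1:2) {
      mask <- which(p$fold == f)
      spf <- sp; spf$seed <- 77L + 1000L * p$replicate + f
      spf$standardize <- FALSE
      fit <- fit_gibbs(replace(rec$value, mask, NA), env, ks, spf)
      preds[mask] <- fit$yhat[mask]
    }
    pa <- pearson_within_env(preds, rec$value, rec$environment_id)
    want[p$replicate, pa$environment] <- pa$value
  }
  expect_equal(got$per_replicate, want)
  expect_equal(got$mean, colMeans(want))
})

test_that("CV0 yields one correlation per environment without SD", {
  st <- simulate_study(simulation_config(
    n_b_lines = 5, n_r_lines = 4, n_hybrids = 18, n_loci = 250, n_env = 3,
    seed = 31))
  rec <- st$pheno[st$pheno$genotype_class == "hybrid", ]
  sp <- model_spec(iterations = 600, burn_in = 200, standardize = TRUE)
  r0 <- run_cv(rec, st$ped, st$markers, "CV0", "M1", sp, seed = 9,
               center = TRUE)
  expect_equal(dim(r0$per_replicate), c(1L, 3L))
  expect_true(all(is.na(r0$sd)))
  expect_true(all(is.finite(r0$mean)))
})

test_that("fits are invariant to perturbation of test-fold responses (no leakage)", {
  st <- simulate_study(simulation_config(
    n_b_lines = 4, n_r_lines = 4, n_hybrids = 14, n_loci = 200, n_env = 2,
    seed = 32))
  rec <- st$pheno[st$pheno$genotype_class == "hybrid", ]
  sp <- model_spec(iterations = 500, burn_in = 100, standardize = TRUE)
  r1 <- run_cv(rec, st$ped, st$markers, "CV1", "M1", sp, k = 2, reps = 1,
               seed = 13, center = TRUE)
  # corrupt the responses of one test fold; its predictions must not move
  p <- partition_cv1(rec, k = 2, reps = 1, seed = 13)[[1]]
  rec2 <- rec
  rec2$value[p$fold == 1] <- rec2$value[p$fold == 1] + 1e4
  r2 <- run_cv(rec2, st$ped, st$markers, "CV1", "M1", sp, k = 2, reps = 1,
               seed = 13, center = TRUE)
  # fold 1 was masked in both runs: its predictions are bit-identical,
  # proving the corrupted test responses never entered that fit
  expect_identical(r1$predictions[1, p$fold == 1],
                   r2$predictions[1, p$fold == 1])
  # whereas fold-2 fits trained on the corrupted fold-1 values do move
  expect_false(isTRUE(all.equal(r1$predictions[1, p$fold == 2],
                                r2$predictions[1, p$fold == 2])))
})

test_that("CV2 outperforms CV1 on structured synthetic data (tendency over seeds)", {
  deltas <- vapply(1:10, function(s) {
    st <- simulate_study(simulation_config(
      n_b_lines = 6, n_r_lines = 5, n_hybrids = 24, n_loci = 250, n_env = 2,
      shares = c(E = 0.25, G_P1 = 0.1, G_P2 = 0.15, G_P1xP2 = 0.15,
                 G_P1xE = 0.03, G_P2xE = 0.03, G_P1xP2xE = 0.04, R = 0.25),
      seed = 500 + s))
    rec <- st$pheno[st$pheno$genotype_class == "hybrid", ]
    sp <- model_spec(iterations = 700, burn_in = 200, standardize = TRUE)
    r2 <- run_cv(rec, st$ped, st$markers, "CV2", "M2", sp, k = 2, reps = 2,
                 seed = s, center = TRUE)
    r1 <- run_cv(rec, st$ped, st$markers, "CV1", "M2", sp, k = 2, reps = 2,
                 seed = s, center = TRUE)
    mean(r2$mean) - mean(r1$mean)
  }, numeric(1))
  expect_gt(mean(deltas), 0)
})
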