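# Small fitter instances: one or two environments, explicit kernels.

env_one <- function(n) matrix(1L, n, 1, dimnames = list(NULL, "E1"))

test_that("model_spec validates its settings", {
  expect_error(model_spec(iterations = 100, burn_in = 100), "iterations")
  expect_error(model_spec(thin = 0))
  expect_error(model_spec(df0 = 0))
})

test_that("blup_solve reproduces the ridge and shrinkage limits", {
  set.seed(31)
  n <- 24
  y <- rnorm(n, 10, 2)
  ks <- manual_kernel_set(list(G = diag(n)))
  env <- env_one(n)
  # huge kernel variance: fitted values approach the data
  hi <- blup_solve(y, env, ks, c(E = 1e-6, G = 1e6, R = 1))
  expect_lt(max(abs(hi$fitted - y)), 1e-3 * diff(range(y)))
  # vanishing genetic variance: fitted values approach environment means
  envs <- rep(c("E1", "E2"), each = n / 2)
  z <- build_incidence(
    phenotype_table(data.frame(genotype_id = paste0("g", 1:n),
                               environment_id = envs, value = y,
                               genotype_class = "hybrid")),
    NULL, "environment")
  lo <- blup_solve(y, z, ks, c(E = 1e6, G = 1e-8, R = 1))
  mns <- tapply(y, envs, mean)
  expect_lt(max(abs(lo$fitted - mns[envs])), 1e-2)
})

test_that("blup_solve matches a naive full-inversion oracle", {
  set.seed(17)
  n <- 20
  K1 <- random_psd(n); K2 <- random_psd(n)
  y <- rnorm(n, 5, 1)
  envs <- rep(c("E1", "E2"), each = 10)
  env <- matrix(0L, n, 2, dimnames = list(NULL, c("E1", "E2")))
  env[cbind(1:n, match(envs, c("E1", "E2")))] <- 1L
  ks <- manual_kernel_set(list(A = K1, B = K2))
  v <- c(E = 0.5, A = 0.8, B = 0.3, R = 0.4)
  got <- blup_solve(y, env, ks, v)
  V <- v[["R"]] * diag(n) + v[["E"]] * tcrossprod(env) +
    v[["A"]] * K1 + v[["B"]] * K2
  Vi <- solve(V)
  mu <- sum(Vi %*% y) / sum(Vi)
  r <- y - mu
  expect_equal(got$mu, mu, tolerance = 1e-8)
  expect_equal(got$u$A, as.numeric(v[["A"]] * K1 %*% Vi %*% r), tolerance = 1e-8)
  expect_equal(got$fitted,
               as.numeric(mu + (v[["E"]] * tcrossprod(env) + v[["A"]] * K1 +
                                  v[["B"]] * K2) %*% Vi %*% r),
               tolerance = 1e-8)
})

test_that("the Gibbs sampler is bit-reproducible and bookkeeps its chain", {
  set.seed(5)
  n <- 30
  y <- rnorm(n, 8, 1)
  ks <- manual_kernel_set(list(G = random_psd(n, 44)))
  sp <- model_spec(iterations = 400, burn_in = 100, thin = 3, seed = 99)
  f1 <- fit_gibbs(y, env_one(n), ks, sp)
  f2 <- fit_gibbs(y, env_one(n), ks, sp)
  expect_identical(f1$yhat, f2$yhat)
  expect_identical(f1$var_samples, f2$var_samples)
  expect_equal(f1$n_retained, (400 - 100) %/% 3)
  expect_true(all(f1$var_samples > 0))
})

test_that("a constant response drives predictions to that constant", {
  n <- 40
  y <- rep(c(5, 5), n / 2)
  y[c(3, 17)] <- NA
  ks <- manual_kernel_set(list(G = random_psd(n, 7)))
  f <- fit_gibbs(y, env_one(n), ks,
                 model_spec(iterations = 1500, burn_in = 500, seed = 2))
  expect_lt(max(abs(f$yhat[c(3, 17)] - 5)), 0.5)
})

test_that("with fixed variances the Gibbs posterior mean matches blup_solve", {
  set.seed(61)
  n <- 36
  K <- random_psd(n, 15)
  u_true <- as.numeric(t(chol(K + 1e-8 * diag(n))) %*% rnorm(n))
  y <- 4 + u_true + rnorm(n, 0, 0.5)
  ks <- manual_kernel_set(list(G = K))
  v <- c(E = 0.1, G = 1, R = 0.25)
  oracle <- blup_solve(y, env_one(n), ks, v)
  f <- fit_gibbs(y, env_one(n), ks,
                 model_spec(iterations = 6000, burn_in = 1000, thin = 1,
                            seed = 8, fix_variances = v,
                            keep_effect_samples = TRUE))
  se <- apply(f$fit_samples, 1, hybridGP:::mcse_batch)
  expect_true(all(abs(f$yhat - oracle$fitted) <= 3 * se))
})

test_that("variance decomposition normalizes to 100 and flags pure noise", {
  set.seed(71)
  n <- 60
  y <- rnorm(n)  # no genetic structure
  ks <- manual_kernel_set(list(A = random_psd(n, 3), B = random_psd(n, 4)))
  f <- fit_gibbs(y, env_one(n), ks,
                 model_spec(iterations = 2000, burn_in = 500, seed = 12))
  vd <- variance_decomposition(f)
  expect_equal(sum(vd$percent), 100, tolerance = 0.01)
  expect_true(all(vd$percent >= 0))
  res <- vd$percent[vd$term == "R"]
  expect_true(all(res > vd$percent[vd$term %in% c("A", "B")]))
})

test_that("retained variance chains stabilize (quarter-chain running means)", {
  set.seed(81)
  n <- 50
  K <- random_psd(n, 9)
  y <- as.numeric(t(chol(K + 1e-8 * diag(n))) %*% rnorm(n)) + rnorm(n, 0, 0.6)
  f <- fit_gibbs(y, env_one(n), manual_kernel_set(list(G = K)),
                 model_spec(iterations = 4000, burn_in = 1000, thin = 1, seed = 3))
  vs <- f$var_samples
  m <- nrow(vs)
  q3 <- colMeans(vs[seq_len(3 * m %/% 4), , drop = FALSE])
  q4 <- colMeans(vs)
  expect_true(all(abs(q4 - q3) / q4 < 0.10))
})

test_that("unmasking records tends to improve within-environment accuracy", {
  diffs <- vapply(1:20, function(s) {
    st <- simulate_study(tiny_config(seed = 400 + s,
                                     shares = c(E = 0.2, G_P1 = 0.1, G_P2 = 0.15,
                                                G_P1xP2 = 0.15, G_P1xE = 0.05,
                                                G_P2xE = 0.05, G_P1xP2xE = 0.05,
                                                R = 0.25)))
    rec <- st$pheno[st$pheno$genotype_class == "hybrid", ]
    g <- build_grm(center_markers(st$markers))
    ks <- prepare_kernels(assemble_kernels("M2", rec, st$ped, g, g,
                                           standardize = TRUE))
    env <- build_incidence(rec, st$ped, "environment")
    e1 <- which(rec$environment_id == "E1")
    test_idx <- e1[1:6]; extra <- e1[7:12]
    sp <- model_spec(iterations = 1200, burn_in = 400, seed = s)
    fA <- fit_gibbs(replace(rec$value, c(test_idx, extra), NA), env, ks, sp)
    fB <- fit_gibbs(replace(rec$value, test_idx, NA), env, ks, sp)
    cor(fB$yhat[test_idx], rec$value[test_idx]) -
      cor(fA$yhat[test_idx], rec$value[test_idx])
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})
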