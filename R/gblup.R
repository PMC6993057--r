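#' MCMC and prior settings for the multi-kernel GBLUP fit
#'
#' Variance components get scaled-inverse-chi-squared priors. With prior
#' degrees of freedom `df0`, the prior scale of every random term (each
#' genetic kernel and the environment intercept) is chosen so that the
#' prior mode equals an equal split of a fraction `R2` of the observed
#' phenotypic variance across the random terms; the residual prior mode is
#' the remaining `1 - R2` fraction. This mirrors the common default of
#' Bayesian whole-genome regression software.
#'
#' @param iterations Total Gibbs iterations (default 12000).
#' @param burn_in Discarded initial iterations (default 2000).
#' @param thin Thinning interval (default 5).
#' @param seed Integer seed; the fit is bit-reproducible given the same
#'   seed and settings. `NULL` leaves the RNG state alone.
#' @param df0 Prior degrees of freedom for every variance (default 5).
#' @param R2 Prior fraction of phenotypic variance assigned to the random
#'   terms jointly (default 0.5).
#' @param standardize Standardize kernels (mean diagonal 1) before
#'   fitting? Default `FALSE`.
#' @param fix_variances Optional named numeric vector fixing the variance
#'   components (names: `"E"`, the kernel labels, `"R"` for residual);
#'   when supplied the variance updates are skipped — used for oracle
#'   comparisons against the closed-form mixed-model solution.
#' @param keep_effect_samples Keep the retained samples of the fitted
#'   values (memory proportional to records x retained)? Default `FALSE`.
#' @return A `model_spec` list.
#' @export
model_spec <- function(iterations = 12000, burn_in = 2000, thin = 5,
                       seed = NULL, df0 = 5, R2 = 0.5,
                       standardize = FALSE, fix_variances = NULL,
                       keep_effect_samples = FALSE) {
  stopifnot(iterations > burn_in, burn_in >= 0, thin >= 1, df0 > 0,
            R2 > 0, R2 < 1)
  structure(list(iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = seed, df0 = df0, R2 = R2,
                 standardize = standardize, fix_variances = fix_variances,
                 keep_effect_samples = keep_effect_samples),
            class = "model_spec")
}

# Eigen-decompose each kernel once, truncating eigenvalues below
# tol * max to zero; effects are sampled in the retained eigenspace.
# Attaches $eig to the kernel_set so repeated fits (cross-validation with
# different masks over the same records) reuse the decomposition.
#' Precompute kernel eigendecompositions for repeated fits
#'
#' @param kernels A `kernel_set`.
#' @param tol Relative eigenvalue floor (default 1e-10).
#' @return The `kernel_set` with an `eig` element (per-kernel `vectors`
#'   and `values` of the retained eigenspace).
#' @export
prepare_kernels <- function(kernels, tol = 1e-10) {
  stopifnot(inherits(kernels, "kernel_set"))
  if (!is.null(kernels$eig)) return(kernels)
  kernels$eig <- lapply(kernels$K, function(K) {
    es <- eigen(K, symmetric = TRUE)
    mx <- max(es$values)
    if (min(es$values) < -1e-8 * max(mx, 1))
      stop("kernel is not positive semidefinite beyond tolerance")
    keep <- es$values > tol * mx
    list(vectors = es$vectors[, keep, drop = FALSE],
         values = es$values[keep])
  })
  kernels
}

#' Fit the multi-kernel Bayesian GBLUP model by Gibbs sampling
#'
#' Fits `y = mu + E_j + sum_k u_k + e` where `mu` has a flat prior, the
#' environment intercepts are `E_j ~ N(0, sigma2_E)`, each genetic effect
#' vector is `u_k ~ N(0, C_k sigma2_k)` for a record-level covariance
#' kernel `C_k`, and all variances carry scaled-inverse-chi-squared
#' priors. Effects are sampled in the eigenbasis of each kernel
#' (decomposed once), where the conditional posterior is diagonal.
#' Missing (masked) responses are sampled from their conditional
#' distribution each iteration (Bayesian data augmentation); their
#' posterior-mean linear predictor is the test-set prediction.
#'
#' @param y Numeric response vector; `NA` marks masked records.
#' @param env 0/1 records x environments incidence matrix
#'   (see [build_incidence()]).
#' @param kernels A `kernel_set` over the same records
#'   (optionally pre-processed with [prepare_kernels()]).
#' @param spec A [model_spec()].
#' @return A `model_fit`: posterior means of `mu`, `E`, each `u_k` and the
#'   fitted values (`yhat`), the retained variance samples
#'   (`var_samples`, columns `E`, kernel labels, `R`), their posterior
#'   means/SDs, and bookkeeping fields.
#' @export
fit_gibbs <- function(y, env, kernels, spec = model_spec()) {
  stopifnot(inherits(kernels, "kernel_set"), inherits(spec, "model_spec"))
  n <- length(y)
  if (kernels$n_records != n) stop("kernel dimension does not match length(y)")
  if (nrow(env) != n) stop("env incidence does not match length(y)")
  miss <- which(is.na(y))
  obs <- setdiff(seq_len(n), miss)
  J <- ncol(env)
  if (length(obs) == 0L) stop("all responses are masked")
  if (length(obs) < J + 2L) stop("too few observed responses to fit")
  if (spec$standardize)
    kernels$K <- lapply(kernels$K, function(k) k / mean(diag(k)))
  kernels <- prepare_kernels(kernels)
  if (!is.null(spec$seed)) set.seed(spec$seed)

  labels <- kernels$labels
  nk <- length(labels)
  eig <- kernels$eig
  envidx <- max.col(env, ties.method = "first")
  nj <- as.numeric(colSums(env))
  env_names <- colnames(env)

  fixed <- !is.null(spec$fix_variances)
  if (fixed) {
    fv <- spec$fix_variances
    need <- c("E", labels, "R")
    if (!all(need %in% names(fv)))
      stop("fix_variances needs names: ", paste(need, collapse = ", "))
  }

  # prior scales from the observed phenotypic variance
  vy <- stats::var(y[obs])
  if (!is.finite(vy) || vy <= 0) vy <- 1e-8  # degenerate constant response
  df0 <- spec$df0
  n_random <- nk + 1L
  mode_rand <- spec$R2 * vy / n_random
  S0_rand <- mode_rand * (df0 + 2) / df0
  S0_res <- (1 - spec$R2) * vy * (df0 + 2) / df0

  # state
  mu <- mean(y[obs])
  E <- rep(0, J)
  delta <- lapply(eig, function(e) rep(0, length(e$values)))
  u <- lapply(eig, function(e) rep(0, n))
  s2_E <- if (fixed) fv[["E"]] else mode_rand
  s2_k <- if (fixed) fv[labels] else rep(mode_rand, nk)
  s2_e <- if (fixed) fv[["R"]] else (1 - spec$R2) * vy
  yfull <- y
  yfull[miss] <- mu
  r <- yfull - mu  # running residual: yfull - mu - Z_E E - sum(u)

  n_ret <- (spec$iterations - spec$burn_in) %/% spec$thin
  var_samples <- matrix(NA_real_, n_ret, nk + 2L,
                        dimnames = list(NULL, c("E", labels, "R")))
  sum_mu <- 0; sum_E <- rep(0, J)
  sum_u <- lapply(seq_len(nk), function(i) rep(0, n))
  sum_fit <- rep(0, n); sum_fit2 <- rep(0, n)
  fit_samples <- if (spec$keep_effect_samples)
    matrix(NA_real_, n, n_ret) else NULL
  ret <- 0L

  for (it in seq_len(spec$iterations)) {
    # intercept (flat prior)
    a <- r + mu
    mu <- stats::rnorm(1, mean(a), sqrt(s2_e / n))
    r <- a - mu
    # environment intercepts
    b <- r + E[envidx]
    sj <- rowsum(b, envidx, reorder = TRUE)[, 1L]
    prec <- nj / s2_e + 1 / s2_E
    E <- stats::rnorm(J, (sj / s2_e) / prec, sqrt(1 / prec))
    r <- b - E[envidx]
    if (!fixed)
      s2_E <- (sum(E^2) + df0 * S0_rand) / stats::rchisq(1, df0 + J)
    # genetic kernels, one at a time, in the eigenbasis
    for (k in seq_len(nk)) {
      ek <- eig[[k]]
      e <- r + u[[k]]
      v <- crossprod(ek$vectors, e)[, 1L]
      dsig <- ek$values * s2_k[k]
      ci <- dsig / (dsig + s2_e)
      dk <- stats::rnorm(length(v), ci * v, sqrt(ci * s2_e))
      delta[[k]] <- dk
      u[[k]] <- as.numeric(ek$vectors %*% dk)
      r <- e - u[[k]]
      if (!fixed)
        s2_k[k] <- (sum(dk^2 / ek$values) + df0 * S0_rand) /
          stats::rchisq(1, df0 + length(dk))
    }
    # residual variance (augmented residuals included)
    if (!fixed)
      s2_e <- (sum(r^2) + df0 * S0_res) / stats::rchisq(1, df0 + n)
    # data augmentation for masked responses
    if (length(miss) > 0L) {
      fit_miss <- yfull[miss] - r[miss]
      ynew <- stats::rnorm(length(miss), fit_miss, sqrt(s2_e))
      yfull[miss] <- ynew
      r[miss] <- ynew - fit_miss
    }
    # accumulate
    if (it > spec$burn_in && (it - spec$burn_in) %% spec$thin == 0L) {
      ret <- ret + 1L
      var_samples[ret, ] <- c(s2_E, s2_k, s2_e)
      sum_mu <- sum_mu + mu
      sum_E <- sum_E + E
      fit <- yfull - r
      sum_fit <- sum_fit + fit
      sum_fit2 <- sum_fit2 + fit^2
      for (k in seq_len(nk)) sum_u[[k]] <- sum_u[[k]] + u[[k]]
      if (!is.null(fit_samples)) fit_samples[, ret] <- fit
    }
  }
  var_samples <- var_samples[seq_len(ret), , drop = FALSE]
  yhat <- sum_fit / ret
  yhat_sd <- sqrt(pmax(sum_fit2 / ret - yhat^2, 0))
  Em <- sum_E / ret; names(Em) <- env_names
  structure(list(
    spec = spec, labels = labels, model = kernels$model,
    mu = sum_mu / ret, E = Em,
    u = stats::setNames(lapply(sum_u, function(s) s / ret), labels),
    var_samples = var_samples,
    var_mean = colMeans(var_samples),
    var_sd = apply(var_samples, 2, stats::sd),
    yhat = yhat, yhat_sd = yhat_sd,
    fit_samples = fit_samples,
    missing = miss, n_retained = ret), class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("model_fit %s: %d records (%d masked), %d retained samples\n",
              x$model, length(x$yhat), length(x$missing), x$n_retained))
  print(round(rbind(mean = x$var_mean, sd = x$var_sd), 3))
  invisible(x)
}

#' Closed-form mixed-model solution at fixed variance components
#'
#' Direct Gaussian conditional means for the same model as [fit_gibbs()]
#' with all variances known: with
#' `V = sum_k C_k s2_k + Z_E Z_E' s2_E + s2_e I`, the intercept is the
#' generalized-least-squares estimate and each random-effect vector is
#' `C_k s2_k V^{-1} (y - mu 1)`. Serves as the independent oracle for the
#' Gibbs sampler.
#'
#' @param y Complete numeric response vector (no `NA`).
#' @param env Records x environments incidence matrix.
#' @param kernels A `kernel_set` over the records.
#' @param variances Named numeric vector: `"E"`, one entry per kernel
#'   label, and `"R"` (residual); all positive.
#' @return List with `mu`, `E` (named), `u` (list per kernel), `fitted`.
#' @export
blup_solve <- function(y, env, kernels, variances) {
  stopifnot(inherits(kernels, "kernel_set"))
  if (anyNA(y)) stop("blup_solve needs a complete response vector")
  labels <- kernels$labels
  need <- c("E", labels, "R")
  if (!all(need %in% names(variances)))
    stop("variances needs names: ", paste(need, collapse = ", "))
  if (any(variances[need] <= 0)) stop("all variances must be positive")
  n <- length(y)
  V <- diag(variances[["R"]], n) + tcrossprod(env) * variances[["E"]]
  for (k in labels) V <- V + kernels$K[[k]] * variances[[k]]
  ch <- tryCatch(chol(V), error = function(e) stop("singular V"))
  Vinv_y <- backsolve(ch, forwardsolve(t(ch), y))
  Vinv_1 <- backsolve(ch, forwardsolve(t(ch), rep(1, n)))
  mu <- sum(Vinv_y) / sum(Vinv_1)
  resid <- y - mu
  Vinv_r <- backsolve(ch, forwardsolve(t(ch), resid))
  u <- lapply(labels, function(k)
    as.numeric(kernels$K[[k]] %*% Vinv_r) * variances[[k]])
  names(u) <- labels
  E <- as.numeric(crossprod(env, Vinv_r)) * variances[["E"]]
  names(E) <- colnames(env)
  fitted <- mu + as.numeric(env %*% E) + Reduce(`+`, u)
  list(mu = mu, E = E, u = u, fitted = fitted)
}

#' Posterior variance decomposition
#'
#' Percentage of total variability attributed to each model term
#' (environment, each genetic kernel, residual):
#' `100 * mean(s2_t) / sum_t mean(s2_t)`. The reported uncertainty is the
#' posterior SD of the per-sample percentage.
#'
#' @param fit A `model_fit`.
#' @return Data frame with columns `term`, `percent`, `se`; percentages
#'   sum to 100.
#' @export
variance_decomposition <- function(fit) {
  stopifnot(inherits(fit, "model_fit"))
  vs <- fit$var_samples
  means <- colMeans(vs)
  percent <- 100 * means / sum(means)
  pct_samples <- 100 * vs / rowSums(vs)
  data.frame(term = colnames(vs),
             percent = as.numeric(percent),
             se = as.numeric(apply(pct_samples, 2, stats::sd)),
             row.names = NULL)
}

# Monte-Carlo standard error by batch means (for oracle-equivalence
# checks on retained effect samples).
mcse_batch <- function(x, n_batches = 20) {
  n <- length(x)
  bs <- n %/% n_batches
  if (bs < 2L) return(stats::sd(x) / sqrt(n))
  m <- matrix(x[seq_len(bs * n_batches)], nrow = bs)
  stats::sd(colMeans(m)) / sqrt(n_batches)
}
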