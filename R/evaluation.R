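#' Within-environment predictive ability
#'
#' Pearson correlation between predicted and observed values, computed
#' separately on each environment's records — the standard accuracy
#' measure for multi-environment genomic prediction.
#'
#' @param pred,obs Numeric vectors of equal length.
#' @param env_labels Environment id per entry.
#' @param min_n Minimum records per environment (default 3).
#' @return Data frame with columns `environment`, `value`, `n`. A zero-
#'   variance prediction or observation vector yields `NA` with a warning.
#' @export
pearson_within_env <- function(pred, obs, env_labels, min_n = 3) {
  if (length(pred) != length(obs) || length(obs) != length(env_labels))
    stop("pred, obs and env_labels must have equal length")
  envs <- unique(as.character(env_labels))
  out <- lapply(envs, function(e) {
    i <- which(env_labels == e)
    if (length(i) < min_n)
      stop("environment ", e, " has fewer than ", min_n, " records")
    p <- pred[i]; o <- obs[i]
    if (stats::sd(p) == 0 || stats::sd(o) == 0) {
      warning("zero variance in environment ", e, "; correlation undefined")
      v <- NA_real_
    } else v <- stats::cor(p, o)
    data.frame(environment = e, value = v, n = length(i))
  })
  do.call(rbind, out)
}

#' Mean and SD of predictive ability across replicates
#'
#' @param per_replicate Numeric matrix, replicates x environments (or a
#'   vector for a single environment). `NA` replicates (undefined
#'   correlations) are excluded.
#' @return Data frame with columns `environment`, `mean`, `sd`; `sd` is
#'   `NA` with a single replicate (sample SD, n - 1 denominator).
#' @export
summarize_replicates <- function(per_replicate) {
  m <- as.matrix(per_replicate)
  if (is.null(colnames(m))) colnames(m) <- paste0("env", seq_len(ncol(m)))
  data.frame(environment = colnames(m),
             mean = as.numeric(colMeans(m, na.rm = TRUE)),
             sd = as.numeric(apply(m, 2, function(x) {
               x <- x[!is.na(x)]
               if (length(x) < 2L) NA_real_ else stats::sd(x)
             })),
             row.names = NULL)
}
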