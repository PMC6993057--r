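#' Genomic relationship matrix from inbred allele counts
#'
#' Computes `G = X X' / p` where `X` is the lines x loci matrix of
#' major-allele copy numbers and `p` the number of loci. This is the
#' literal cross-product form (no column centering, no diagonal scaling);
#' set `standardize = TRUE` to divide by the mean diagonal so that the
#' average self-relationship is 1, which makes variance components
#' comparable across kernels.
#'
#' @param m A `marker_matrix`, imputed (and normally MAF-filtered).
#' @param standardize Divide by the mean diagonal? Default `FALSE`.
#' @return A `relationship_kernel`: list with `values` (symmetric line x
#'   line matrix), `entity_ids`, `label`.
#' @export
build_grm <- function(m, standardize = FALSE) {
  stopifnot(inherits(m, "marker_matrix"))
  if (anyNA(m$counts)) stop("marker matrix has missing entries; impute first")
  p <- ncol(m$counts)
  if (p < 1L) stop("no loci in marker matrix")
  G <- tcrossprod(m$counts) / p
  if (standardize) G <- G / mean(diag(G))
  relationship_kernel(G, label = "G")
}

#' Construct a relationship kernel
#'
#' @param values Symmetric positive semidefinite matrix with identical
#'   row/column names (the entity ids).
#' @param label Term name.
#' @param check Validate symmetry and positive semidefiniteness.
#' @return A `relationship_kernel` object.
#' @export
relationship_kernel <- function(values, label = "", check = TRUE) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("kernel needs entity ids as dimnames")
  if (check) {
    if (!isSymmetric(values, tol = 1e-8))
      stop("kernel is not symmetric")
    ev <- eigen(values, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev), 1))
      stop("kernel is not positive semidefinite")
  }
  structure(list(values = values, entity_ids = rownames(values),
                 label = label),
            class = "relationship_kernel")
}

#' @export
print.relationship_kernel <- function(x, ...) {
  cat(sprintf("relationship_kernel '%s': %d entities, mean diagonal %.3f\n",
              x$label, nrow(x$values), mean(diag(x$values))))
  invisible(x)
}

#' Incidence matrix mapping records to factor levels
#'
#' Builds the 0/1 records x levels matrix for one classification of the
#' phenotype records: the parent-1 line, the parent-2 line, the
#' environment, or the genotype itself. Every row has exactly one 1;
#' column order follows first appearance in the records.
#'
#' @param records A phenotype table (one row per record).
#' @param ped A pedigree table (needed for the parent keys).
#' @param key One of `"parent1"`, `"parent2"`, `"environment"`,
#'   `"genotype"`.
#' @return Integer 0/1 matrix, `nrow(records)` x number of levels, with
#'   level ids as colnames.
#' @export
build_incidence <- function(records, ped,
                            key = c("parent1", "parent2", "environment", "genotype")) {
  key <- match.arg(key)
  records <- phenotype_table(records)
  lev_of <- switch(key,
    environment = records$environment_id,
    genotype = records$genotype_id,
    {
      ped <- pedigree_table(ped)
      col <- if (key == "parent1") "p1_id" else "p2_id"
      idx <- match(records$genotype_id, ped$genotype_id)
      if (anyNA(idx))
        stop("genotype without pedigree row: ",
             paste(unique(records$genotype_id[is.na(idx)]), collapse = ", "))
      ped[[col]][idx]
    })
  levels <- unique(lev_of)
  Z <- matrix(0L, nrow = length(lev_of), ncol = length(levels),
              dimnames = list(NULL, levels))
  Z[cbind(seq_along(lev_of), match(lev_of, levels))] <- 1L
  Z
}

#' Hadamard (cell-by-cell) product of two covariance structures
#'
#' Elementwise product of two equally sized matrices. By the Schur product
#' theorem the result is positive semidefinite whenever both inputs are.
#'
#' @param a,b Matrices of identical dimension.
#' @return Their elementwise product.
#' @export
hadamard <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("hadamard: dimension mismatch")
  a * b
}

#' Expand an entity-level kernel to record level
#'
#' Given an entity kernel `K` and an incidence map `Z` from records to
#' entities, returns `Z K Z'`: the records x records covariance whose
#' (r, s) entry is `K[level(r), level(s)]`.
#'
#' @param k A `relationship_kernel`.
#' @param z Incidence matrix from [build_incidence()]; its colnames must
#'   all be entities of `k`.
#' @return A records x records matrix.
#' @export
expand_kernel <- function(k, z) {
  stopifnot(inherits(k, "relationship_kernel"))
  miss <- setdiff(colnames(z), k$entity_ids)
  if (length(miss) > 0L)
    stop("incidence level(s) absent from kernel: ", paste(miss, collapse = ", "))
  K <- k$values[colnames(z), colnames(z), drop = FALSE]
  # Z K Z' via row lookup: each record's row of K, then column lookup
  lev <- max.col(z, ties.method = "first")
  K[lev, lev, drop = FALSE]
}

#' Assemble the record-level covariance kernels of models M1-M3
#'
#' The three nested hybrid-prediction models share an environment random
#' intercept (handled separately by the fitter) and differ in their
#' genetic covariance terms:
#' \describe{
#'   \item{M1}{GCA main effects only: `G_P1`, `G_P2` expanded to records.}
#'   \item{M2}{M1 plus the SCA term
#'     `(Z1 G_P1 Z1') o (Z2 G_P2 Z2')` (Hadamard product).}
#'   \item{M3}{M2 plus the three genotype-by-environment interactions,
#'     each the Hadamard product of the corresponding record-level genetic
#'     kernel with the environment co-membership matrix `Z_E Z_E'`.}
#' }
#' All interactions are formed uniformly at record level, which is
#' invariant to record ordering and coincides with the block-diagonal
#' Kronecker form when records are sorted by environment.
#'
#' @param model `"M1"`, `"M2"` or `"M3"`.
#' @param records Phenotype table defining the record order.
#' @param ped Pedigree table for the genotypes in `records`.
#' @param g1 `relationship_kernel` covering every parent-1 line (for
#'   inbred-augmented records, the inbred itself).
#' @param g2 `relationship_kernel` covering every parent-2 line. May be the
#'   same (joint) kernel object as `g1`.
#' @param standardize Divide each assembled record-level kernel by its mean
#'   diagonal? Default `FALSE` (literal formulas).
#' @return A `kernel_set`: list with `model`, `labels`, `K` (named list of
#'   records x records matrices), `n_records`.
#' @export
assemble_kernels <- function(model = c("M1", "M2", "M3"), records, ped, g1, g2,
                             standardize = FALSE) {
  model <- match.arg(model)
  records <- phenotype_table(records)
  z1 <- build_incidence(records, ped, "parent1")
  z2 <- build_incidence(records, ped, "parent2")
  ze <- build_incidence(records, ped, "environment")
  K1 <- expand_kernel(g1, z1)
  K2 <- expand_kernel(g2, z2)
  K <- list(G_P1 = K1, G_P2 = K2)
  if (model %in% c("M2", "M3"))
    K$G_P1xP2 <- hadamard(K1, K2)
  if (model == "M3") {
    EE <- tcrossprod(ze)  # 1 iff two records share an environment
    K$G_P1xE <- hadamard(K$G_P1, EE)
    K$G_P2xE <- hadamard(K$G_P2, EE)
    K$G_P1xP2xE <- hadamard(K$G_P1xP2, EE)
  }
  if (standardize)
    K <- lapply(K, function(k) k / mean(diag(k)))
  structure(list(model = model, labels = names(K), K = K,
                 n_records = nrow(records)),
            class = "kernel_set")
}

#' @export
print.kernel_set <- function(x, ...) {
  cat(sprintf("kernel_set %s: %d records, terms: %s\n",
              x$model, x$n_records, paste(x$labels, collapse = ", ")))
  invisible(x)
}

#' Export a kernel as square CSV
#'
#' @param k A `relationship_kernel` or plain square matrix with dimnames.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_kernel_csv <- function(k, path) {
  v <- if (inherits(k, "relationship_kernel")) k$values else as.matrix(k)
  utils::write.csv(as.data.frame(v), path, row.names = TRUE)
  invisible(path)
}

#' Import a kernel from square CSV
#'
#' @param path CSV written by [write_kernel_csv()].
#' @param label Term name for the result.
#' @return A `relationship_kernel`.
#' @export
read_kernel_csv <- function(path, label = "") {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  relationship_kernel(as.matrix(df), label = label)
}
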