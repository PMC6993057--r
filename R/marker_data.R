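#' Construct a marker matrix of inbred allele counts
#'
#' A `marker_matrix` holds major-allele copy numbers for a panel of inbred
#' lines: one row per line, one column per locus. For fully inbred lines the
#' observed codes are 0 or 2 copies of the major allele; missing calls are
#' `NA` until [impute_mean()] is applied, after which fractional values in
#' \[0, 2\] are permitted.
#'
#' @param counts Numeric matrix, lines x loci, with unique non-empty
#'   rownames (line ids) and colnames (locus ids). `NA` entries allowed.
#' @param platform_tag Free-text label for the genotyping platform
#'   (e.g. `"C"` or `"T"`).
#' @return An object of class `marker_matrix`: a list with elements
#'   `counts` and `platform_tag`.
#' @seealso [read_marker_matrix()], [impute_mean()], [filter_maf()]
#' @export
marker_matrix <- function(counts, platform_tag = "") {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("marker matrix needs line ids (rownames) and locus ids (colnames)")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate line id: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate locus id: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  rng <- range(counts, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2))
    stop("allele counts must lie in [0, 2]")
  structure(list(counts = counts, platform_tag = platform_tag),
            class = "marker_matrix")
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat(sprintf("marker_matrix: %d lines x %d loci%s, %d missing entries\n",
              nrow(x$counts), ncol(x$counts),
              if (nzchar(x$platform_tag)) paste0(" [", x$platform_tag, "]") else "",
              sum(is.na(x$counts))))
  invisible(x)
}

#' @export
dim.marker_matrix <- function(x) dim(x$counts)

#' Line identifiers of a marker matrix
#' @param m A `marker_matrix`.
#' @return Character vector of line ids.
#' @export
line_ids <- function(m) rownames(m$counts)

#' Locus identifiers of a marker matrix
#' @param m A `marker_matrix`.
#' @return Character vector of locus ids.
#' @export
locus_ids <- function(m) colnames(m$counts)

#' Read a marker matrix from a delimited table or VCF
#'
#' Delimited input: header row of locus ids, first column the line id,
#' remaining columns allele counts (empty cells or `NA` mark missing calls).
#' VCF input: biallelic SNPs only; diploid genotype calls are converted to
#' copies of the major allele, where the major allele at each site is the
#' more frequent allele among the non-missing calls in the file (ties go to
#' the reference allele).
#'
#' @param path Path to the input file.
#' @param format `"delimited"` (CSV/TSV, autodetected separator) or `"vcf"`.
#' @param platform_tag Optional platform label stored in the result.
#' @return A [marker_matrix()] with missing calls preserved as `NA`.
#' @export
read_marker_matrix <- function(path, format = c("delimited", "vcf"),
                               platform_tag = "") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "delimited") {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            check.names = FALSE, stringsAsFactors = FALSE,
                            na.strings = c("NA", ""))
    if (ncol(df) < 2L) stop("cannot parse marker table: ", path)
    ids <- as.character(df[[1L]])
    x <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(x)) stop("non-numeric allele counts in ", path)
    rownames(x) <- ids
    marker_matrix(x, platform_tag)
  } else {
    read_marker_vcf(path, platform_tag)
  }
}

# VCF ingestion via vcfR; genotypes oriented to the major allele per site.
read_marker_vcf <- function(path, platform_tag = "") {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  fix <- vcfR::getFIX(v)
  alt <- fix[, "ALT"]
  if (any(grepl(",", alt)))
    stop("multiallelic site in VCF; only biallelic SNPs are supported")
  # ALT-allele dosage per call
  dose <- apply(gt, c(1, 2), function(g) {
    if (is.na(g)) return(NA_real_)
    al <- strsplit(g, "[/|]")[[1L]]
    if (any(al == ".")) return(NA_real_)
    sum(al == "1")
  })
  dose <- matrix(as.numeric(dose), nrow = nrow(gt), dimnames = dimnames(gt))
  # orient each locus to its major allele; tie (f = 0.5) keeps REF major
  alt_freq <- rowMeans(dose, na.rm = TRUE) / 2
  ref_major <- alt_freq <= 0.5
  dose[ref_major, ] <- 2 - dose[ref_major, , drop = FALSE]
  loci <- rownames(gt)
  if (is.null(loci) || anyNA(loci))
    loci <- paste0(fix[, "CHROM"], "_", fix[, "POS"])
  out <- t(dose)
  colnames(out) <- loci
  marker_matrix(out, platform_tag)
}

#' Write a marker matrix as a delimited table
#'
#' Inverse of [read_marker_matrix()] for the delimited format.
#'
#' @param m A `marker_matrix`.
#' @param path Output path; `.tsv` extension selects tab separation,
#'   anything else comma.
#' @return `path`, invisibly.
#' @export
write_marker_matrix <- function(m, path) {
  stopifnot(inherits(m, "marker_matrix"))
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- data.frame(line_id = line_ids(m), m$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Mean-impute missing marker calls
#'
#' Replaces each missing entry by the mean of the non-missing allele counts
#' at that locus; observed entries are untouched. Imputed values may be
#' fractional, which downstream relationship-matrix algebra accepts.
#'
#' @param m A `marker_matrix`.
#' @return A `marker_matrix` with no missing entries.
#' @export
impute_mean <- function(m) {
  stopifnot(inherits(m, "marker_matrix"))
  x <- m$counts
  all_na <- colSums(!is.na(x)) == 0L
  if (any(all_na))
    stop("locus with no observed calls: ",
         paste(colnames(x)[all_na], collapse = ", "))
  if (!anyNA(x)) return(m)
  mu <- colMeans(x, na.rm = TRUE)
  idx <- which(is.na(x), arr.ind = TRUE)
  x[idx] <- mu[idx[, 2L]]
  marker_matrix(x, m$platform_tag)
}

#' Filter loci on minor allele frequency
#'
#' The allele frequency of the major allele at a locus is
#' `mean(counts) / 2` over all lines; the minor allele frequency (MAF) is
#' `min(f, 1 - f)`. Loci with MAF strictly below `threshold` are excluded,
#' so a locus sitting exactly at the threshold is retained. Locus order is
#' preserved.
#'
#' @param m A `marker_matrix` with no missing entries (impute first).
#' @param threshold MAF exclusion threshold in \[0, 0.5\]; default 0.05.
#' @return A `marker_matrix` restricted to the retained loci.
#' @export
filter_maf <- function(m, threshold = 0.05) {
  stopifnot(inherits(m, "marker_matrix"))
  if (threshold < 0 || threshold > 0.5)
    stop("MAF threshold must lie in [0, 0.5]")
  if (anyNA(m$counts)) stop("marker matrix has missing entries; impute first")
  f <- colMeans(m$counts) / 2
  maf <- pmin(f, 1 - f)
  keep <- maf >= threshold
  marker_matrix(m$counts[, keep, drop = FALSE], m$platform_tag)
}

#' Validate a pedigree table
#'
#' A pedigree table maps every genotype to its two parents. Hybrid rows
#' carry distinct parents drawn from two disjoint pools (seed parent /
#' B-line as parent 1, pollinator / R-line as parent 2); inbred rows are
#' self-referential (`p1_id == p2_id == genotype_id`), the representation
#' used when parental inbreds are modeled as self-crosses.
#'
#' @param ped Data frame with columns `genotype_id`, `p1_id`, `p2_id`,
#'   `genotype_class` (values `"hybrid"` or `"inbred"`).
#' @return The validated data frame (character columns), invisibly classed.
#' @export
pedigree_table <- function(ped) {
  need <- c("genotype_id", "p1_id", "p2_id", "genotype_class")
  if (!all(need %in% names(ped)))
    stop("pedigree table needs columns: ", paste(need, collapse = ", "))
  ped <- as.data.frame(ped, stringsAsFactors = FALSE)
  for (cl in need) ped[[cl]] <- as.character(ped[[cl]])
  if (anyDuplicated(ped$genotype_id))
    stop("duplicate genotype_id in pedigree")
  if (!all(ped$genotype_class %in% c("hybrid", "inbred")))
    stop("genotype_class must be 'hybrid' or 'inbred'")
  hy <- ped$genotype_class == "hybrid"
  if (any(ped$p1_id[hy] == ped$p2_id[hy]))
    stop("hybrid rows must have two distinct parents")
  if (length(intersect(ped$p1_id[hy], ped$p2_id[hy])) > 0L)
    stop("parent-1 and parent-2 pools must be disjoint")
  inb <- !hy
  ok_self <- ped$p1_id[inb] == ped$genotype_id[inb] &
    ped$p2_id[inb] == ped$genotype_id[inb]
  if (!all(ok_self))
    stop("inbred rows must have p1_id == p2_id == genotype_id")
  ped
}

#' Validate a long-format phenotype table
#'
#' @param pheno Data frame with columns `genotype_id`, `environment_id`,
#'   `value` (trait, e.g. grain yield in kg/ha), `genotype_class`.
#' @return The validated data frame.
#' @export
phenotype_table <- function(pheno) {
  need <- c("genotype_id", "environment_id", "value", "genotype_class")
  if (!all(need %in% names(pheno)))
    stop("phenotype table needs columns: ", paste(need, collapse = ", "))
  pheno <- as.data.frame(pheno, stringsAsFactors = FALSE)
  pheno$genotype_id <- as.character(pheno$genotype_id)
  pheno$environment_id <- as.character(pheno$environment_id)
  pheno$genotype_class <- as.character(pheno$genotype_class)
  pheno$value <- as.numeric(pheno$value)
  if (anyDuplicated(pheno[, c("genotype_id", "environment_id")]))
    stop("at most one record per (genotype, environment)")
  pheno
}

#' Restrict to genotypes observed in every environment with full marker data
#'
#' Multi-environment analyses here require a complete genotype x environment
#' layout: a genotype is kept only if it has a phenotype record in every
#' environment present in the table and every parent referenced by its
#' pedigree row has a marker profile. Everything else is dropped and
#' counted.
#'
#' @param pheno A phenotype table (see [phenotype_table()]).
#' @param ped A pedigree table covering all genotypes in `pheno`.
#' @param markers A `marker_matrix` (or list of them) whose lines must cover
#'   the parents of retained genotypes.
#' @param quiet Suppress the dropped-genotype message.
#' @return List with elements `pheno`, `ped` (both restricted), and
#'   `dropped` (character vector of removed genotype ids).
#' @export
align_complete_cases <- function(pheno, ped, markers, quiet = FALSE) {
  pheno <- phenotype_table(pheno)
  ped <- pedigree_table(ped)
  if (inherits(markers, "marker_matrix")) markers <- list(markers)
  envs <- unique(pheno$environment_id)
  if (length(envs) < 1L) stop("no environments present")
  counts <- table(pheno$genotype_id)
  complete <- names(counts)[counts == length(envs)]
  # require presence in all environments, not just the right count
  tab <- table(pheno$genotype_id, pheno$environment_id)
  complete <- rownames(tab)[rowSums(tab > 0) == length(envs)]
  has_markers <- vapply(seq_len(nrow(ped)), function(i) {
    all(vapply(markers, function(m)
      all(c(ped$p1_id[i], ped$p2_id[i]) %in% line_ids(m)), logical(1)))
  }, logical(1))
  genotyped <- ped$genotype_id[has_markers]
  keep <- intersect(complete, genotyped)
  if (length(keep) == 0L) stop("no genotype is complete in all environments with markers")
  dropped <- setdiff(unique(pheno$genotype_id), keep)
  if (!quiet && length(dropped) > 0L)
    message(length(dropped), " genotype(s) dropped (incomplete environments or missing markers)")
  list(pheno = pheno[pheno$genotype_id %in% keep, , drop = FALSE],
       ped = ped[ped$genotype_id %in% keep, , drop = FALSE],
       dropped = dropped)
}
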