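# library normalization: median-of-ratios, TMM, FPKM

#' Median-of-ratios size factors
#'
#' For each sample, the median over all-positive genes of the ratio of its
#' count to the gene's geometric mean across samples (the DESeq-style
#' pseudo-reference). Identical columns get identical factors; scaling a
#' library by c scales its factor by c exactly.
#'
#' @param counts Non-negative gene x sample matrix.
#' @param pseudo_reference If no gene is positive in every sample, fall back
#'   to computing the geometric mean over positive entries only (default
#'   FALSE: error instead).
#' @return Named vector of positive size factors.
#' @export
size_factors_median_of_ratios <- function(counts, pseudo_reference = FALSE) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts")
  allpos <- rowSums(counts <= 0) == 0L
  if (!any(allpos)) {
    if (!pseudo_reference)
      stop("no gene has positive counts in every sample; ",
           "set pseudo_reference = TRUE to use positive-entry geometric means")
    loggeo <- apply(counts, 1, function(x) mean(log(x[x > 0])))
    use <- is.finite(loggeo)
    lr <- log(counts[use, , drop = FALSE]) - loggeo[use]
    sf <- apply(lr, 2, function(x) exp(stats::median(x[is.finite(x)])))
  } else {
    loggeo <- rowMeans(log(counts[allpos, , drop = FALSE]))
    sf <- apply(log(counts[allpos, , drop = FALSE]) - loggeo, 2,
                function(x) exp(stats::median(x)))
  }
  stats::setNames(sf, colnames(counts))
}

#' Trimmed mean of M-values (TMM) normalization factors
#'
#' Weighted trimmed mean of per-gene log2 ratios against a reference sample:
#' 30% two-sided trim on M (log-ratio), 5% on A (average log abundance),
#' inverse-variance precision weights. Factors are composition factors on top
#' of library-size scaling and are normalized to geometric mean 1.
#'
#' @param counts Non-negative gene x sample matrix.
#' @param reference Reference sample name/index, or `"auto"` (column whose
#'   upper quartile of scaled counts is closest to the mean upper quartile).
#' @param trim_m,trim_a Two-sided trim fractions.
#' @return Named vector of positive factors with geometric mean 1.
#' @export
tmm_factors <- function(counts, reference = "auto", trim_m = 0.3, trim_a = 0.05) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("TMM needs at least two samples")
  lib <- colSums(counts)
  if (any(lib == 0)) stop("zero library size")
  if (identical(reference, "auto")) {
    uq <- apply(counts, 2, function(x) stats::quantile(x[x > 0], 0.75)) / lib
    reference <- which.min(abs(uq - mean(uq)))
  }
  r <- if (is.character(reference)) match(reference, colnames(counts)) else reference
  if (is.na(r)) stop("reference sample not found")
  yr <- counts[, r]; Nr <- lib[r]
  f <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    y <- counts[, j]; N <- lib[j]
    ok <- y > 0 & yr > 0
    if (!any(ok)) stop("no genes with positive counts in both sample ",
                       j, " and the reference")
    M <- log2((y[ok] / N) / (yr[ok] / Nr))
    A <- 0.5 * log2((y[ok] / N) * (yr[ok] / Nr))
    w <- 1 / ((N - y[ok]) / (N * y[ok]) + (Nr - yr[ok]) / (Nr * yr[ok]))
    keep <- M > stats::quantile(M, trim_m) & M < stats::quantile(M, 1 - trim_m) &
            A > stats::quantile(A, trim_a) & A < stats::quantile(A, 1 - trim_a)
    f[j] <- if (any(keep)) 2^(sum(w[keep] * M[keep]) / sum(w[keep])) else 1
  }
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(counts))
}

#' Normalized counts
#' @param counts Gene x sample matrix.
#' @param size_factors Per-sample factors (e.g. median-of-ratios); for TMM,
#'   pass `tmm_factors(counts) * colSums(counts) / mean(colSums(counts))`.
#' @return Matrix of counts divided column-wise by the factors.
#' @export
normalize_counts <- function(counts, size_factors = size_factors_median_of_ratios(counts)) {
  sweep(as.matrix(counts), 2, size_factors, "/")
}

#' FPKM
#'
#' Fragments per kilobase of gene per million library fragments:
#' `count / (length/1e3) / (library_size/1e6)`.
#'
#' @param counts Gene x sample matrix.
#' @param gene_lengths Named (or positionally matched) lengths in bp, > 0.
#' @param library_sizes Per-sample totals; defaults to column sums.
#' @return FPKM matrix.
#' @export
compute_fpkm <- function(counts, gene_lengths, library_sizes = colSums(counts)) {
  counts <- as.matrix(counts)
  if (!is.null(names(gene_lengths)) && !is.null(rownames(counts)))
    gene_lengths <- gene_lengths[rownames(counts)]
  if (length(gene_lengths) != nrow(counts)) stop("gene_lengths do not match rows")
  if (any(gene_lengths <= 0) || anyNA(gene_lengths)) stop("gene lengths must be > 0")
  if (any(library_sizes <= 0)) stop("zero library size")
  sweep(counts / (gene_lengths / 1e3), 2, library_sizes / 1e6, "/")
}
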