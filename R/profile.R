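# male-median fold changes and LOESS moving-average profiles along a
# chromosome

#' Male-median reference expression
#'
#' Per-gene median FPKM across the reference 46,XY samples (the MM of the
#' fold-change definition), computed after removing nonexpressed genes:
#' a gene is kept when FPKM >= `min_fpkm` in at least `min_fraction` of the
#' reference samples and its median is > 0.
#'
#' @param fpkm Gene x sample FPKM matrix.
#' @param reference_samples Column names/indices of the 46,XY reference set.
#' @param min_fpkm,min_fraction Expression filter on the reference samples.
#' @return Named vector of MM values (> 0) for retained genes; the number of
#'   excluded genes is attached as attribute `n_excluded`.
#' @export
male_median <- function(fpkm, reference_samples, min_fpkm = 0.5,
                        min_fraction = 0.25) {
  m <- as.matrix(fpkm)
  ref <- m[, reference_samples, drop = FALSE]
  if (ncol(ref) == 0L) stop("empty reference sample set")
  expressed <- rowMeans(ref >= min_fpkm) >= min_fraction
  mm <- apply(ref[expressed, , drop = FALSE], 1, stats::median)
  keep <- mm > 0
  out <- mm[keep]
  attr(out, "n_excluded") <- nrow(m) - length(out)
  out
}

#' Fold changes from the male median
#'
#' FC = FPKM / MM per gene and sample; the reference-group median FC is 1 per
#' gene by construction. Only genes with an MM are retained.
#'
#' @param fpkm Gene x sample FPKM matrix.
#' @param mm Named MM vector from [male_median()].
#' @return Gene x sample fold-change matrix.
#' @export
fold_change_matrix <- function(fpkm, mm) {
  m <- as.matrix(fpkm)
  genes <- intersect(rownames(m), names(mm))
  m[genes, , drop = FALSE] / mm[genes]
}

#' Profile configuration
#' @param span LOESS span in (0,1]; the sliding window is
#'   `ceil(span * n)` nearest observations (study value 0.45).
#' @param reference_group Karyotype label of the reference samples.
#' @param exclude_par1 Drop PAR1 genes before fitting (the alternative
#'   profile that exposes NPX behaviour next to PAR1).
#' @return `profile_config` list.
#' @export
profile_config <- function(span = 0.45, reference_group = "46,XY",
                           exclude_par1 = FALSE) {
  stopifnot(span > 0, span <= 1)
  structure(list(span = span, reference_group = reference_group,
                 exclude_par1 = exclude_par1), class = "profile_config")
}

# local linear regression with tricube weights over the k nearest neighbours
# of each evaluation point; degree-0 fallback when the window is degenerate
.loess_fit_at <- function(x, y, x0, k) {
  d <- abs(x - x0)
  idx <- order(d, x)[seq_len(k)]
  dmax <- max(d[idx])
  w <- if (dmax == 0) rep(1, k) else (1 - pmin(d[idx] / dmax, 1)^3)^3
  w[w < 0] <- 0
  if (sum(w > 0) < 2L || stats::var(x[idx]) == 0) {
    if (all(w == 0)) w <- rep(1, k)
    return(sum(w * y[idx]) / sum(w))
  }
  xw <- x[idx] - x0
  sw <- sum(w); swx <- sum(w * xw); swx2 <- sum(w * xw^2)
  swy <- sum(w * y[idx]); swxy <- sum(w * xw * y[idx])
  den <- sw * swx2 - swx^2
  if (den <= .Machine$double.eps * sw * swx2)
    return(swy / sw)
  (swx2 * swy - swx * swxy) / den
}

#' LOESS moving-average profile along a chromosome
#'
#' Locally weighted linear regression (tricube kernel, no robustness
#' iterations) of log2 fold change against gene position, evaluated at every
#' gene; the window holds `ceil(span * n)` nearest observations.
#'
#' @param position Gene midpoints in bp.
#' @param log2fc Per-gene log2 fold change from the male median.
#' @param gene_id Optional gene ids carried through.
#' @param config A [profile_config()].
#' @param territory Optional per-gene territory used by `exclude_par1`.
#' @return data.frame sorted by position: `gene_id`, `position`,
#'   `log2fc_from_male_median`, `smoothed`.
#' @export
loess_profile <- function(position, log2fc, gene_id = NULL,
                          config = profile_config(), territory = NULL) {
  stopifnot(length(position) == length(log2fc))
  if (is.null(gene_id)) gene_id <- sprintf("g%05d", seq_along(position))
  keep <- is.finite(position) & is.finite(log2fc)
  if (isTRUE(config$exclude_par1)) {
    if (is.null(territory)) stop("exclude_par1 requires per-gene territories")
    keep <- keep & territory != "PAR1"
  }
  x <- position[keep]; y <- log2fc[keep]; g <- gene_id[keep]
  n <- length(x)
  if (n < 5L) stop("need >= 5 points for a profile")
  k <- max(2L, min(n, ceiling(config$span * n)))
  o <- order(x)
  x <- x[o]; y <- y[o]; g <- g[o]
  sm <- vapply(x, function(x0) .loess_fit_at(x, y, x0, k), numeric(1))
  data.frame(gene_id = g, position = x, log2fc_from_male_median = y,
             smoothed = sm, stringsAsFactors = FALSE)
}

#' Full male-median profile of a chromosome for one sample group
#'
#' Convenience pipeline: MM on the reference group, FC matrix, per-gene
#' median log2 FC within the plotted group, then the LOESS profile over the
#' genes of one chromosome.
#'
#' @param fpkm Gene x sample FPKM matrix.
#' @param meta Metadata with `sample_id` and `karyotype`.
#' @param genes GeneRecord data.frame (positions/territories).
#' @param group Karyotype label to profile.
#' @param chrom Chromosome (default `"chrX"`).
#' @param config A [profile_config()].
#' @param cap_quantile FC = 0 entries are -Inf in log2; they are capped at
#'   this quantile of the finite values (plotting convention).
#' @return [loess_profile()] output for the group.
#' @export
group_profile <- function(fpkm, meta, genes, group, chrom = "chrX",
                          config = profile_config(), cap_quantile = 0.005) {
  ref <- meta$sample_id[meta$karyotype == config$reference_group]
  mm <- male_median(fpkm, ref)
  fc <- fold_change_matrix(fpkm, mm)
  smp <- meta$sample_id[meta$karyotype == group]
  if (!length(smp)) stop("no samples with karyotype ", group)
  med_fc <- apply(fc[, smp, drop = FALSE], 1, stats::median)
  l2 <- log2(med_fc)
  if (any(!is.finite(l2))) {
    cap <- stats::quantile(l2[is.finite(l2)], cap_quantile)
    l2[!is.finite(l2)] <- cap
  }
  gi <- genes[match(names(l2), genes$gene_id), ]
  on_chrom <- !is.na(gi$chrom) & gi$chrom == chrom
  loess_profile(position = (gi$start + gi$end)[on_chrom] / 2,
                log2fc = l2[on_chrom], gene_id = names(l2)[on_chrom],
                config = config, territory = gi$territory[on_chrom])
}
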