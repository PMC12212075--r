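# Y-dosage sensitivity: per-gene Pearson correlation of normalized
# expression with Y-chromosome count across karyotypes

#' Per-gene correlation of expression with Y-chromosome count
#'
#' Pearson r of normalized expression against the number of Y chromosomes
#' per sample (the Y ~ E screen), with a two-sided t test (df = n - 2) and
#' Benjamini-Hochberg adjustment over tested genes. Zero-variance genes are
#' flagged and excluded from the adjustment. The same machinery accepts nX
#' for X-dosage analyses.
#'
#' @param norm_expr Gene x sample matrix of normalized expression
#'   (median-of-ratios or TMM-scaled; optionally log2(x+1) via `log`).
#' @param y_counts Integer Y count per sample (>= 2 distinct values).
#' @param log Take log2(norm + 1) before correlating (default FALSE; TMM
#'   values are correlated directly).
#' @param r_threshold,fdr_threshold Sensitivity rule: |r| > 0.48 and
#'   FDR < 0.01.
#' @return data.frame sorted by gene_id: `gene_id`, `r`, `p_value`, `fdr`,
#'   `sensitive`, `reason` (NA or "zero_variance").
#' @export
dosage_correlation <- function(norm_expr, y_counts, log = FALSE,
                               r_threshold = 0.48, fdr_threshold = 0.01) {
  m <- as.matrix(norm_expr)
  stopifnot(length(y_counts) == ncol(m))
  if (ncol(m) < 3L) stop("need >= 3 samples")
  if (length(unique(y_counts)) < 2L)
    stop("all samples share one Y count; correlation undefined")
  if (log) m <- log2(m + 1)
  y <- as.numeric(y_counts)
  yc <- y - mean(y)
  sy <- sqrt(sum(yc^2))
  xc <- m - rowMeans(m)
  sx <- sqrt(rowSums(xc^2))
  r <- as.vector(xc %*% yc) / (sx * sy)
  zero_var <- sx == 0
  r[zero_var] <- NA_real_
  n <- ncol(m)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  res <- data.frame(gene_id = rownames(m), r = r, p_value = p,
                    stringsAsFactors = FALSE)
  res <- res[order(res$gene_id), ]
  res$fdr <- NA_real_
  tested <- !is.na(res$r)
  res$fdr[tested] <- .bh(res$p_value[tested])
  res$sensitive <- tested & !is.na(res$fdr) &
    res$fdr < fdr_threshold & abs(res$r) > r_threshold
  res$reason <- ifelse(tested, NA_character_, "zero_variance")
  rownames(res) <- NULL
  res
}

#' Select dosage-sensitive genes
#'
#' Membership rule: FDR < `fdr_threshold` and |r| > `r_threshold`.
#'
#' @param results [dosage_correlation()] output.
#' @param r_threshold,fdr_threshold Thresholds (0.48, 0.01).
#' @return Character vector of sensitive gene ids.
#' @export
select_dosage_sensitive <- function(results, r_threshold = 0.48,
                                    fdr_threshold = 0.01) {
  hit <- !is.na(results$r) & !is.na(results$fdr) &
    results$fdr < fdr_threshold & abs(results$r) > r_threshold
  sort(results$gene_id[hit])
}

#' Intersect dosage-sensitive genes with a DEG set
#'
#' @param sensitive,degs Character gene sets drawn from the same universe.
#' @return List: `genes` (sorted intersection), `n_sensitive`, `n_degs`,
#'   `n_intersection`. Warns when the sets are disjoint despite both being
#'   non-empty (possible universe mismatch).
#' @export
intersect_with_degs <- function(sensitive, degs) {
  inter <- sort(intersect(sensitive, degs))
  if (length(sensitive) && length(degs) && !length(inter))
    warning("dosage-sensitive and DEG sets are disjoint; check that both ",
            "come from the same gene universe")
  list(genes = inter, n_sensitive = length(unique(sensitive)),
       n_degs = length(unique(degs)), n_intersection = length(inter))
}
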