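# sample QC, data-driven low-expression filtering, NB-Wald differential
# expression and DEG calling at the study thresholds

#' Differential-expression thresholds
#'
#' Defaults are the study rule: FDR < 0.05 together with |log2FC| > 0.58
#' (~1.5-fold); `strict_fdr` = 0.01 is the threshold used where a stricter
#' FDR is called for (dosage-sensitivity intersection).
#'
#' @param fdr_threshold,lfc_threshold,strict_fdr Positive reals.
#' @return A `de_config` list.
#' @export
de_config <- function(fdr_threshold = 0.05, lfc_threshold = 0.58,
                      strict_fdr = 0.01) {
  stopifnot(fdr_threshold > 0, lfc_threshold > 0, strict_fdr > 0)
  structure(list(fdr_threshold = fdr_threshold, lfc_threshold = lfc_threshold,
                 strict_fdr = strict_fdr), class = "de_config")
}

#' Sample quality control on sequencing statistics
#'
#' Keeps a sample iff it has at least 16 million input reads and at least 75%
#' of reads assigned to genes.
#'
#' @param read_stats data.frame with columns `sample_id`, `input_reads`,
#'   `assigned_fraction`.
#' @param samples Optional vector of sample ids that must all be present;
#'   a missing one is an error naming it.
#' @param min_reads,min_assigned The QC cutoffs.
#' @return Character vector of kept sample ids.
#' @export
sample_qc <- function(read_stats, samples = NULL,
                      min_reads = 16e6, min_assigned = 0.75) {
  stopifnot(all(c("sample_id", "input_reads", "assigned_fraction") %in%
                names(read_stats)))
  if (!is.null(samples)) {
    miss <- setdiff(samples, read_stats$sample_id)
    if (length(miss))
      stop("missing read statistics for sample(s): ", paste(miss, collapse = ", "))
    read_stats <- read_stats[read_stats$sample_id %in% samples, ]
  }
  keep <- read_stats$input_reads >= min_reads &
          read_stats$assigned_fraction >= min_assigned
  read_stats$sample_id[keep]
}

#' Data-driven low-expression filter
#'
#' Chooses the normalized-count threshold s* that maximizes the mean
#' between-replicate Jaccard similarity of binary (count > s) expression
#' calls over a log-spaced grid, then removes genes whose normalized count is
#' <= s* in every sample (the HTSFilter idea).
#'
#' @param counts Gene x sample count matrix.
#' @param groups Group label per column; Jaccard is averaged over
#'   within-group sample pairs only.
#' @param size_factors Normalization factors (median-of-ratios by default).
#' @param s_grid Candidate thresholds; default 40 log-spaced points in
#'   [0.1, 200].
#' @return List: `counts` (filtered matrix), `s_star`, and `grid`
#'   (data.frame of threshold vs mean Jaccard).
#' @export
filter_low_expression <- function(counts, groups,
                                  size_factors = size_factors_median_of_ratios(counts),
                                  s_grid = exp(seq(log(0.1), log(200), length.out = 40))) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("filtering needs >= 2 samples (similarity undefined)")
  stopifnot(length(groups) == ncol(counts))
  norm <- normalize_counts(counts, size_factors)
  pairs <- do.call(cbind, lapply(unique(groups), function(g) {
    ix <- which(groups == g)
    if (length(ix) >= 2) utils::combn(ix, 2) else NULL
  }))
  if (is.null(pairs)) stop("no within-group sample pair; cannot assess similarity")
  jac <- vapply(s_grid, function(s) {
    B <- norm > s
    mean(apply(pairs, 2, function(p) {
      u <- sum(B[, p[1]] | B[, p[2]])
      if (u == 0) 1 else sum(B[, p[1]] & B[, p[2]]) / u
    }))
  }, numeric(1))
  s_star <- s_grid[which.max(jac)]
  keep <- rowSums(norm > s_star) > 0L
  list(counts = counts[keep, , drop = FALSE], s_star = s_star,
       grid = data.frame(threshold = s_grid, jaccard = jac))
}

# method-of-moments NB dispersion, pooled within groups on the normalized
# scale, with a 1/mu + const trend fitted across genes for shrinkage
.nb_dispersions <- function(norm, groups, size_factors, shrink_weight = 0.2) {
  lv <- unique(groups)
  G <- nrow(norm)
  mu_all <- rowMeans(norm)
  ss <- 0; df <- 0; bias <- 0
  for (g in lv) {
    ix <- which(groups == g)
    mg <- rowMeans(norm[, ix, drop = FALSE])
    ss <- ss + rowSums((norm[, ix, drop = FALSE] - mg)^2)
    df <- df + length(ix) - 1L
    # shot-noise part of Var(q) = mu/s + alpha mu^2
    bias <- bias + mg * sum(1 / size_factors[ix]) * (length(ix) - 1L) / length(ix)
  }
  s2 <- ss / df
  mom <- (s2 - bias / df) / mu_all^2
  mom[!is.finite(mom)] <- NA
  use <- is.finite(mom) & mu_all > 1
  a0 <- 1e-3; a1 <- 1
  if (sum(use) >= 10) {
    fit <- stats::lm(pmax(mom[use], 1e-8) ~ I(1 / mu_all[use]))
    a0 <- max(unname(fit$coefficients[1]), 1e-4)
    a1 <- max(unname(fit$coefficients[2]), 0)
  }
  trend <- a0 + a1 / pmax(mu_all, 1e-8)
  alpha <- shrink_weight * pmax(ifelse(is.na(mom), trend, mom), 0) +
    (1 - shrink_weight) * trend
  pmax(alpha, 1e-8)
}

#' Negative-binomial Wald differential expression test
#'
#' Per gene: normalized counts via size factors, gene-wise method-of-moments
#' NB dispersion shrunk toward a fitted mean-dispersion trend (floored at
#' 1e-8), and a Wald test on the log2 fold change of group means. The fold
#' change uses a pseudo-count of 0.5 so zero-mean groups stay finite. The
#' trend shrinkage stabilizes the per-gene dispersion enough that the Wald
#' statistic is referred to the standard normal; Benjamini-Hochberg
#' adjustment is applied over all tested genes.
#'
#' @param counts Gene x sample count matrix.
#' @param groups Group label per column (exactly two levels).
#' @param contrast Length-2 character `c(case, control)`; log2FC is
#'   case over control. Defaults to the two group levels in order of first
#'   appearance.
#' @param size_factors Per-sample normalization factors.
#' @param config A [de_config()] used to flag DEGs.
#' @return data.frame sorted by gene_id: `gene_id`, `mean_expression`
#'   (mean normalized count), `log2_fold_change`, `p_value`, `fdr`, `is_deg`.
#' @export
nb_differential_test <- function(counts, groups, contrast = NULL,
                                 size_factors = size_factors_median_of_ratios(counts),
                                 config = de_config()) {
  counts <- as.matrix(counts)
  stopifnot(length(groups) == ncol(counts))
  groups <- as.character(groups)
  if (is.null(contrast)) contrast <- unique(groups)[1:2]
  if (length(unique(groups)) != 2L || !all(sort(unique(groups)) == sort(contrast)))
    stop("groups must have exactly the two contrast levels")
  n1 <- sum(groups == contrast[1]); n2 <- sum(groups == contrast[2])
  if (n1 < 2L || n2 < 2L) stop("each group needs >= 2 samples")
  norm <- normalize_counts(counts, size_factors)
  alpha <- .nb_dispersions(norm, groups, size_factors)
  i1 <- groups == contrast[1]; i2 <- groups == contrast[2]
  mu1 <- rowMeans(norm[, i1, drop = FALSE])
  mu2 <- rowMeans(norm[, i2, drop = FALSE])
  lfc <- log2((mu1 + 0.5) / (mu2 + 0.5))
  l2 <- log(2)^2
  vlog <- function(mu, ii, n) (mean(1 / size_factors[ii]) / (mu + 0.5) + alpha) / (n * l2)
  se <- sqrt(vlog(mu1, i1, n1) + vlog(mu2, i2, n2))
  z <- lfc / se
  p <- 2 * stats::pnorm(-abs(z))
  p[mu1 + mu2 == 0] <- 1
  res <- data.frame(gene_id = rownames(counts), mean_expression = rowMeans(norm),
                    log2_fold_change = lfc, p_value = p, stringsAsFactors = FALSE)
  res <- res[order(res$gene_id), ]
  res$fdr <- .bh(res$p_value)
  res$is_deg <- res$fdr < config$fdr_threshold &
    abs(res$log2_fold_change) > config$lfc_threshold
  rownames(res) <- NULL
  res
}

#' Call differentially expressed genes at the study thresholds
#'
#' DEG iff `fdr < fdr_threshold` and `|log2FC| > lfc_threshold`; direction is
#' the sign of the fold change.
#'
#' @param results A DEResult data.frame ([nb_differential_test()] output).
#' @param config A [de_config()]; pass `fdr = config$strict_fdr` analyses via
#'   the `fdr` override.
#' @param fdr Optional FDR cutoff overriding the config.
#' @return data.frame `gene_id`, `log2_fold_change`, `direction` ("up"/"down")
#'   for the called genes, sorted by gene_id.
#' @export
call_degs <- function(results, config = de_config(), fdr = NULL) {
  stopifnot(all(c("gene_id", "log2_fold_change", "fdr") %in% names(results)))
  cut <- if (is.null(fdr)) config$fdr_threshold else fdr
  hit <- !is.na(results$fdr) & results$fdr < cut &
    abs(results$log2_fold_change) > config$lfc_threshold
  out <- results[hit, c("gene_id", "log2_fold_change")]
  out$direction <- ifelse(out$log2_fold_change > 0, "up", "down")
  out <- out[order(out$gene_id), ]
  rownames(out) <- NULL
  out
}
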