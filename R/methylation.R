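# RRBS differential methylation: per-CpG beta-binomial Wald test, DMR
# seeding/merging at the study rules, annotation and DMR x DEG crosstabs

#' DMR-calling configuration
#'
#' Study rules: per-locus significance p < 1e-5, minimum span 50 bp, minimum
#' three CpGs, regions within 50 bp merged, and at least 50% significant
#' CpGs throughout the merged length. `min_effect` (0.1) and `max_intra_gap`
#' (100 bp) are declared conventions, not study values.
#'
#' @param locus_p_threshold,min_length,min_cpgs,merge_distance,min_sig_fraction,min_effect,max_intra_gap
#'   See description; all positive, `min_sig_fraction` in (0, 1].
#' @return `dmr_config` list.
#' @export
dmr_config <- function(locus_p_threshold = 1e-5, min_length = 50,
                       min_cpgs = 3L, merge_distance = 50,
                       min_sig_fraction = 0.5, min_effect = 0.1,
                       max_intra_gap = 100) {
  stopifnot(locus_p_threshold > 0, min_length > 0, min_cpgs > 0,
            merge_distance > 0, min_sig_fraction > 0, min_sig_fraction <= 1,
            min_effect >= 0, max_intra_gap > 0)
  structure(as.list(environment()), class = "dmr_config")
}

#' Per-CpG two-group beta-binomial differential test
#'
#' For each CpG with coverage in >= 2 samples of each group: group methylation
#' proportions are depth-weighted means; a per-CpG method-of-moments
#' overdispersion, moderated toward the cross-locus median (floored at 1e-6),
#' inflates the binomial variance; the Wald statistic tests the difference of
#' group proportions. CpGs with zero total coverage in a whole group are
#' skipped (counted in attribute `n_skipped`).
#'
#' @param cpgs Long table: `chrom`, `pos`, `sample_id`, `group`,
#'   `methylated`, `total`.
#' @param groups Length-2 character `c(case, control)`; `mean_diff` is case
#'   minus control.
#' @param prior_df Pseudo-degrees of freedom of the cross-locus dispersion
#'   moderation; per-CpG estimates are shrunk toward the genome-wide median
#'   with this weight (0 disables moderation).
#' @return data.frame sorted by chrom, pos: `chrom`, `pos`, `p_value`,
#'   `mean_diff`, `n_samples`.
#' @export
cpg_differential_test <- function(cpgs, groups = NULL, prior_df = 20) {
  need <- c("chrom", "pos", "sample_id", "group", "methylated", "total")
  stopifnot(all(need %in% names(cpgs)))
  if (any(cpgs$methylated > cpgs$total)) stop("methylated > total")
  if (is.null(groups)) groups <- unique(cpgs$group)[1:2]
  key <- paste(cpgs$chrom, cpgs$pos)
  i1 <- cpgs$group == groups[1]
  i2 <- cpgs$group == groups[2]
  ks <- sort(unique(key))
  # per-group per-CpG: depth-weighted proportion and Williams-type MoM
  # overdispersion, vectorized over CpGs via rowsum()
  stat_group <- function(ii) {
    use <- ii & cpgs$total > 0
    k <- key[use]
    t <- as.numeric(cpgs$total[use]); m <- as.numeric(cpgs$methylated[use])
    rs <- rowsum(cbind(t = t, m = m, one = rep(1, length(t)), t2 = t^2,
                       tt1 = t * (t - 1)), k)
    ix <- match(ks, rownames(rs))
    Tt <- rs[ix, "t"]; Mm <- rs[ix, "m"]; n <- rs[ix, "one"]
    T2 <- rs[ix, "t2"]; W <- rs[ix, "tt1"]
    p <- Mm / Tt
    pk <- p[match(k, ks)]
    den <- t * pk * (1 - pk)
    contrib <- ifelse(den > 0, (m - t * pk)^2 / den, 0)
    x2 <- rowsum(contrib, k)
    X2 <- x2[match(ks, rownames(x2)), 1]
    valid <- !is.na(n) & n >= 2 & p > 0 & p < 1 & (Tt - T2 / Tt) > 0
    raw <- ifelse(valid, (X2 - (n - 1)) / (Tt - T2 / Tt), NA_real_)
    # per-CpG MoM at 3 samples is extremely noisy and skewed: moderate toward
    # the aggregate cross-locus MoM with prior_df pseudo-degrees of freedom
    pool <- sum(X2[valid] - (n[valid] - 1)) /
      sum(Tt[valid] - T2[valid] / Tt[valid])
    if (!is.finite(pool)) pool <- 0
    df <- pmax(n - 1, 0)
    rho <- ifelse(is.na(raw), pool,
                  (df * raw + prior_df * pool) / (df + prior_df))
    rho <- pmin(pmax(rho, 1e-6), 0.99)
    v <- p * (1 - p) * (Tt + W * rho) / Tt^2
    cbind(p = p, var = v, n = n)
  }
  s1 <- stat_group(i1)
  s2 <- stat_group(i2)
  ok <- !is.na(s1[, "n"]) & !is.na(s2[, "n"]) & s1[, "n"] >= 2 & s2[, "n"] >= 2
  diff <- s1[, "p"] - s2[, "p"]
  se <- sqrt(s1[, "var"] + s2[, "var"])
  z <- ifelse(se > 0, diff / se, ifelse(diff == 0, 0, Inf * sign(diff)))
  p <- 2 * stats::pnorm(-abs(z))
  first <- match(ks, key)
  out <- data.frame(chrom = cpgs$chrom[first], pos = cpgs$pos[first],
                    p_value = unname(p), mean_diff = unname(diff),
                    n_samples = unname(s1[, "n"] + s2[, "n"]),
                    stringsAsFactors = FALSE)[ok, ]
  out <- out[order(out$chrom, out$pos), ]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- sum(!ok)
  out
}

# merge step factored out so idempotence is testable on its own
.merge_regions <- function(reg, merge_distance) {
  if (nrow(reg) <= 1L) return(reg)
  reg <- reg[order(reg$chrom, reg$start), ]
  out <- reg[1, ]
  for (i in 2:nrow(reg)) {
    last <- nrow(out)
    if (reg$chrom[i] == out$chrom[last] &&
        reg$start[i] - out$end[last] <= merge_distance) {
      out$end[last] <- max(out$end[last], reg$end[i])
    } else {
      out <- rbind(out, reg[i, ])
    }
  }
  out
}

#' Call differentially methylated regions
#'
#' (1) a CpG is significant iff p < `locus_p_threshold` and |mean_diff| >=
#' `min_effect`; (2) seeds are maximal runs of significant CpGs with
#' consecutive gaps <= `max_intra_gap`, bounded by the first and last
#' significant CpG; (3) seeds spanning < `min_length` bp or holding fewer
#' than `min_cpgs` CpGs (significant or not, within bounds) are dropped;
#' (4) surviving regions within `merge_distance` bp on one chromosome are
#' merged; (5) merged regions must keep >= `min_sig_fraction` significant
#' CpGs over their whole length. Direction is the sign of the mean difference
#' over the region's significant CpGs.
#'
#' @param cpg_results [cpg_differential_test()] output, position-sorted per
#'   chromosome (unsorted input is an error).
#' @param config A [dmr_config()].
#' @return data.frame: `chrom`, `start`, `end`, `n_cpgs`, `n_sig_cpgs`,
#'   `sig_fraction`, `mean_diff`, `direction`, `min_p`.
#' @export
call_dmrs <- function(cpg_results, config = dmr_config()) {
  cr <- cpg_results
  stopifnot(all(c("chrom", "pos", "p_value", "mean_diff") %in% names(cr)))
  empty <- data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                      n_cpgs = integer(0), n_sig_cpgs = integer(0),
                      sig_fraction = numeric(0), mean_diff = numeric(0),
                      direction = character(0), min_p = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(cr) == 0L) return(empty)
  for (ch in unique(cr$chrom)) {
    p <- cr$pos[cr$chrom == ch]
    if (is.unsorted(p)) stop("CpG positions unsorted on ", ch)
  }
  sig <- cr$p_value < config$locus_p_threshold &
    abs(cr$mean_diff) >= config$min_effect
  # seeds: runs of significant CpGs with gaps <= max_intra_gap
  seeds <- list()
  si <- which(sig)
  if (length(si)) {
    brk <- c(TRUE, cr$chrom[si[-1]] != cr$chrom[si[-length(si)]] |
               cr$pos[si[-1]] - cr$pos[si[-length(si)]] > config$max_intra_gap)
    run <- cumsum(brk)
    for (r in unique(run)) {
      ix <- si[run == r]
      seeds[[length(seeds) + 1L]] <- data.frame(
        chrom = cr$chrom[ix[1]], start = cr$pos[ix[1]],
        end = cr$pos[ix[length(ix)]], stringsAsFactors = FALSE)
    }
  }
  if (!length(seeds)) return(empty)
  reg <- do.call(rbind, seeds)
  count_cpgs <- function(reg) {
    n <- integer(nrow(reg))
    for (i in seq_len(nrow(reg)))
      n[i] <- sum(cr$chrom == reg$chrom[i] & cr$pos >= reg$start[i] &
                    cr$pos <= reg$end[i])
    n
  }
  keep <- (reg$end - reg$start) >= config$min_length &
    count_cpgs(reg) >= config$min_cpgs
  reg <- reg[keep, , drop = FALSE]
  if (!nrow(reg)) return(empty)
  reg <- .merge_regions(reg, config$merge_distance)
  out <- list()
  for (i in seq_len(nrow(reg))) {
    inr <- cr$chrom == reg$chrom[i] & cr$pos >= reg$start[i] &
      cr$pos <= reg$end[i]
    n_all <- sum(inr); n_sig <- sum(inr & sig)
    frac <- n_sig / n_all
    if (frac < config$min_sig_fraction) next
    md <- mean(cr$mean_diff[inr & sig])
    out[[length(out) + 1L]] <- data.frame(
      chrom = reg$chrom[i], start = reg$start[i], end = reg$end[i],
      n_cpgs = n_all, n_sig_cpgs = n_sig, sig_fraction = frac,
      mean_diff = md, direction = if (md >= 0) "hyper" else "hypo",
      min_p = min(cr$p_value[inr & sig]), stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Annotate DMRs against a gene annotation
#'
#' Region class per DMR midpoint: `promoter` when inside the strand-aware TSS
#' window (default -2000/+500 bp), else `gene_body` when inside a gene, else
#' `intergenic`; promoter takes precedence. The nearest assigned gene id is
#' reported for promoter/gene-body DMRs.
#'
#' @param dmrs [call_dmrs()] output.
#' @param genes GeneRecord data.frame (needs `strand`).
#' @param promoter_upstream,promoter_downstream TSS window in bp.
#' @return `dmrs` with `region_class` and `gene_id` columns.
#' @export
annotate_dmrs <- function(dmrs, genes, promoter_upstream = 2000,
                          promoter_downstream = 500) {
  if (!nrow(dmrs)) {
    dmrs$region_class <- character(0); dmrs$gene_id <- character(0)
    return(dmrs)
  }
  strand <- if (is.null(genes$strand)) rep("+", nrow(genes)) else genes$strand
  tss <- ifelse(strand == "-", genes$end, genes$start)
  pstart <- ifelse(strand == "-", tss - promoter_downstream, tss - promoter_upstream)
  pend <- ifelse(strand == "-", tss + promoter_upstream, tss + promoter_downstream)
  cls <- character(nrow(dmrs)); gid <- rep(NA_character_, nrow(dmrs))
  for (i in seq_len(nrow(dmrs))) {
    mid <- (dmrs$start[i] + dmrs$end[i]) / 2
    same <- genes$chrom == dmrs$chrom[i]
    in_prom <- same & mid >= pstart & mid <= pend
    in_body <- same & mid >= genes$start & mid <= genes$end
    if (any(in_prom)) {
      cls[i] <- "promoter"; gid[i] <- genes$gene_id[which(in_prom)[1]]
    } else if (any(in_body)) {
      cls[i] <- "gene_body"; gid[i] <- genes$gene_id[which(in_body)[1]]
    } else cls[i] <- "intergenic"
  }
  dmrs$region_class <- cls
  dmrs$gene_id <- gid
  dmrs
}

#' DMR x DEG contingency per region class
#'
#' For promoter and gene-body DMRs assigned to DEGs: 2x2 counts of
#' methylation direction (hyper/hypo) against expression direction (up/down)
#' with a Haldane-corrected odds ratio (0.5 added to every cell when any is
#' zero); all-zero tables report `NA`.
#'
#' @param annotated_dmrs [annotate_dmrs()] output.
#' @param degs [call_degs()] output (`gene_id`, `direction`).
#' @return Named list per region class: `table` (2x2) and `odds_ratio`.
#' @export
dmr_deg_crosstab <- function(annotated_dmrs, degs) {
  out <- list()
  for (cls in c("promoter", "gene_body")) {
    d <- annotated_dmrs[annotated_dmrs$region_class == cls &
                          !is.na(annotated_dmrs$gene_id), , drop = FALSE]
    m <- matrix(0, 2, 2, dimnames = list(meth = c("hyper", "hypo"),
                                         expr = c("up", "down")))
    if (nrow(d)) {
      ix <- match(d$gene_id, degs$gene_id)
      hit <- !is.na(ix)
      if (any(hit)) {
        tb <- table(factor(d$direction[hit], c("hyper", "hypo")),
                    factor(degs$direction[ix[hit]], c("up", "down")))
        m <- m + as.matrix(tb)
      }
    }
    or <- if (sum(m) == 0) NA_real_ else {
      mm <- if (any(m == 0)) m + 0.5 else m
      (mm[1, 1] * mm[2, 2]) / (mm[1, 2] * mm[2, 1])
    }
    out[[cls]] <- list(table = m, odds_ratio = or)
  }
  out
}

#' Read a Bismark-coverage-style CpG table
#'
#' Either the 6-column coverage dialect (chrom, start, end, pct, methylated,
#' unmethylated) or a 4-column (chrom, pos, methylated, total) TSV.
#'
#' @param path File path.
#' @param sample_id,group Labels attached to every row.
#' @param dialect `"coverage"` (methylated + unmethylated) or `"counts"`
#'   (methylated + total).
#' @return Long CpG data.frame as consumed by [cpg_differential_test()].
#' @export
read_cpg_table <- function(path, sample_id, group, dialect = c("coverage", "counts")) {
  dialect <- match.arg(dialect)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (dialect == "coverage") {
    if (ncol(df) < 6L) stop("coverage dialect needs 6 columns")
    data.frame(chrom = df[[1]], pos = df[[2]], sample_id = sample_id,
               group = group, methylated = df[[5]], total = df[[5]] + df[[6]],
               stringsAsFactors = FALSE)
  } else {
    if (ncol(df) < 4L) stop("counts dialect needs 4 columns")
    data.frame(chrom = df[[1]], pos = df[[2]], sample_id = sample_id,
               group = group, methylated = df[[3]], total = df[[4]],
               stringsAsFactors = FALSE)
  }
}

#' Write DMRs as BED6+
#'
#' name = direction, score = -log10 of the smallest locus p (capped at 1000),
#' extra columns n_cpgs, sig_fraction, mean_diff.
#'
#' @param dmrs [call_dmrs()] output.
#' @param path Output path.
#' @export
write_dmr_bed <- function(dmrs, path) {
  score <- pmin(round(-log10(pmax(dmrs$min_p, 1e-300))), 1000)
  out <- data.frame(dmrs$chrom, dmrs$start, dmrs$end, dmrs$direction, score,
                    ".", dmrs$n_cpgs, signif(dmrs$sig_fraction, 4),
                    signif(dmrs$mean_diff, 4))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
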