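# cross-syndrome concordance: shared DEGs between two contrasts and the
# direction-interaction classification

#' Shared DEGs between two contrasts
#' @param degs_a,degs_b Character gene sets (same universe).
#' @return Sorted character intersection.
#' @export
shared_degs <- function(degs_a, degs_b) sort(intersect(degs_a, degs_b))

#' Direction-concordance interaction analysis
#'
#' Classifies each shared DEG by the signs of its fold changes in the two
#' contrasts: concordant up (both > 0), concordant down (both < 0), else
#' discordant. A zero fold change cannot occur for a DEG (the |log2FC|
#' threshold excludes it) and is asserted against, not assumed.
#'
#' @param shared Character vector of shared genes.
#' @param lfc_a,lfc_b Named log2 fold-change vectors covering every shared
#'   gene (a missing one is an error naming it).
#' @return List: `total_shared`, `concordant_up`, `concordant_down`,
#'   `discordant`, `pct_concordant` (full precision),
#'   `pct_concordant_integer`, and `classes` (per-gene classification).
#' @export
interaction_classification <- function(shared, lfc_a, lfc_b) {
  miss <- c(setdiff(shared, names(lfc_a)), setdiff(shared, names(lfc_b)))
  if (length(miss))
    stop("missing log2FC for gene(s): ", paste(unique(miss), collapse = ", "))
  a <- lfc_a[shared]; b <- lfc_b[shared]
  if (any(a == 0 | b == 0))
    stop("zero log2FC among shared DEGs; DEG thresholds should exclude this")
  cls <- ifelse(a > 0 & b > 0, "concordant_up",
                ifelse(a < 0 & b < 0, "concordant_down", "discordant"))
  up <- sum(cls == "concordant_up"); down <- sum(cls == "concordant_down")
  total <- length(shared)
  pct <- if (total) 100 * (up + down) / total else NA_real_
  list(total_shared = total, concordant_up = up, concordant_down = down,
       discordant = total - up - down, pct_concordant = pct,
       pct_concordant_integer = if (total) as.integer(pct %/% 1) else NA_integer_,
       classes = stats::setNames(cls, shared))
}

#' Interaction summary from printed contingency counts
#'
#' The same arithmetic applied to already-tabulated counts (total shared,
#' concordant up, concordant down), for summarising published tallies.
#'
#' @param total,up,down Non-negative integers with `up + down <= total`.
#' @return Same structure as [interaction_classification()] minus `classes`.
#' @export
interaction_from_counts <- function(total, up, down) {
  stopifnot(total >= 0, up >= 0, down >= 0, up + down <= total)
  pct <- if (total) 100 * (up + down) / total else NA_real_
  list(total_shared = total, concordant_up = up, concordant_down = down,
       discordant = total - up - down, pct_concordant = pct,
       pct_concordant_integer = if (total) as.integer(pct %/% 1) else NA_integer_)
}
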