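# signed standardized Mann-Whitney statistic with tie correction.
# z > 0 iff group x tends to have larger values than group y.
rank_sum_z <- function(x, y) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(c(z = 0, p = 1))
  z <- (U - mu) / sqrt(sigma2)
  c(z = z, p = 2 * stats::pnorm(-abs(z)))
}

enrichment_table <- function(comp, idx_a, idx_b, alpha) {
  if (length(idx_a) < 2L || length(idx_b) < 2L)
    stop("both groups need at least 2 LCRs")
  rows <- lapply(AA20, function(aa) {
    zp <- rank_sum_z(comp$matrix[idx_a, aa], comp$matrix[idx_b, aa])
    data.frame(residue = aa, z_score = unname(zp["z"]),
               p_value = unname(zp["p"]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_adjusted < alpha
  structure(out, class = c("enrichment_result", "data.frame"),
            alpha = alpha)
}

#' Residue enrichment of annotated LCRs versus all other LCRs
#'
#' For each of the 20 standard amino acids, a two-sided Wilcoxon rank-sum
#' test (normal approximation with tie correction) compares the residue's
#' frequency in the annotated LCRs against all remaining LCRs. Positive
#' z-scores mean the residue is enriched in the annotated set. P-values
#' are Benjamini-Hochberg adjusted across the 20 residues.
#'
#' @param comp an `lcr_composition`.
#' @param annotated_mask logical (or integer index) selecting the
#'   annotated rows; the complement is the comparison group.
#' @param alpha significance level on the adjusted p-value, default 0.001.
#' @return data.frame (class `enrichment_result`) with one row per
#'   residue: residue, z_score, p_value, p_adjusted, significant
#' @export
rank_sum_enrichment <- function(comp, annotated_mask, alpha = 0.001) {
  check_composition(comp)
  n <- nrow(comp$matrix)
  idx_a <- seq_len(n)[annotated_mask]
  idx_b <- setdiff(seq_len(n), idx_a)
  enrichment_table(comp, idx_a, idx_b, alpha)
}

#' Residue enrichment between two annotation sets of LCRs
#'
#' Head-to-head comparison of two LCR groups, with B as the reference:
#' positive z-scores mean enrichment in A. Rows belonging to both groups
#' are excluded (their count is reported with a message), since the
#' rank-sum test assumes independent groups.
#'
#' @param comp an `lcr_composition`.
#' @param mask_a,mask_b logical masks (or indices) over the rows.
#' @param alpha significance level, default 0.001.
#' @return data.frame as in [rank_sum_enrichment()]
#' @export
pairwise_enrichment <- function(comp, mask_a, mask_b, alpha = 0.001) {
  check_composition(comp)
  n <- nrow(comp$matrix)
  idx_a <- seq_len(n)[mask_a]
  idx_b <- seq_len(n)[mask_b]
  both <- intersect(idx_a, idx_b)
  if (length(both) > 0L) {
    message(length(both), " LCR(s) in both sets excluded")
    idx_a <- setdiff(idx_a, both)
    idx_b <- setdiff(idx_b, both)
  }
  enrichment_table(comp, idx_a, idx_b, alpha)
}

#' Select annotated rows of a composition matrix
#'
#' @param comp an `lcr_composition`.
#' @param annotation an `annotation_set` (or character vector of ids).
#' @return logical mask over rows: TRUE where the LCR's protein is in the
#'   annotation
#' @export
annotation_mask <- function(comp, annotation) {
  check_composition(comp)
  ids <- if (inherits(annotation, "annotation_set"))
    annotation$protein_ids else as.character(annotation)
  comp$meta$protein_id %in% ids
}
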