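## Two-group differential expression on normalized log2 values: per-gene
## Welch t-tests with Benjamini-Hochberg control and a fold-change bound.

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement; a thin, validating
#' wrapper over `p.adjust(method = "BH")` that preserves input order.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values, same order and length.
#' @export
bh_adjust <- function(p_values) {
  gk_assert(all(p_values >= 0 & p_values <= 1, na.rm = TRUE),
            "p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Differential expression between two accession groups
#'
#' Per gene: Welch (unequal-variance) two-sample t-test of group A versus
#' group B on normalized log2 expression; BH adjustment across all tested
#' genes; log2 fold-change as the difference of group means on the log2
#' scale.  A gene is significant when `q < fdr_threshold` and
#' `|log2fc| > lfc_threshold` (both strict, mirroring the study thresholds
#' FDR < 0.01 and |log2FC| > 2).
#'
#' Genes with zero variance in both groups get `p = 1` when the means are
#' equal; with unequal means the variance is floored at 1e-12 (such genes
#' are perfectly separated and their p-values underflow to 0).
#'
#' @param expr an [expression_matrix()] on the `normalized` scale.
#' @param groups an accession [grouping()].
#' @param group_a,group_b cluster ids to contrast (A minus B).
#' @param fdr_threshold,lfc_threshold significance bounds (defaults 0.01, 2).
#' @return data.frame with one row per gene: `gene_id`, `mean_a`, `mean_b`,
#'   `log2fc`, `t_stat`, `df`, `p_value`, `q_value`, `significant`.
#' @export
differential_expression <- function(expr, groups, group_a, group_b,
                                    fdr_threshold = 0.01, lfc_threshold = 2) {
  gk_assert(inherits(expr, "expression_matrix") && expr$scale == "normalized",
            "expr must be a normalized-scale expression_matrix")
  a_ids <- intersect(group_members(groups, group_a), colnames(expr$values))
  b_ids <- intersect(group_members(groups, group_b), colnames(expr$values))
  gk_assert(length(a_ids) >= 2 && length(b_ids) >= 2,
            "both groups need >= 2 accessions with expression")
  xa <- expr$values[, a_ids, drop = FALSE]
  xb <- expr$values[, b_ids, drop = FALSE]
  na <- ncol(xa); nb <- ncol(xb)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- apply(xa, 1, var); vb <- apply(xb, 1, var)
  degenerate <- va == 0 & vb == 0
  se2 <- va / na + vb / nb
  se2_floored <- pmax(se2, 1e-12)
  t_stat <- (ma - mb) / sqrt(se2_floored)
  df <- se2_floored^2 /
    pmax(va^2 / (na^2 * (na - 1)) + vb^2 / (nb^2 * (nb - 1)), 1e-300)
  p <- 2 * pt(-abs(t_stat), df)
  p[degenerate & ma == mb] <- 1
  if (any(degenerate & ma != mb))
    message(sprintf(
      "differential_expression: %d gene(s) with zero variance in both groups and unequal means (variance floored)",
      sum(degenerate & ma != mb)))
  q <- bh_adjust(p)
  log2fc <- ma - mb
  out <- data.frame(
    gene_id = rownames(expr$values),
    mean_a = ma, mean_b = mb, log2fc = log2fc,
    t_stat = t_stat, df = df, p_value = p, q_value = q,
    significant = q < fdr_threshold & abs(log2fc) > lfc_threshold,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
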