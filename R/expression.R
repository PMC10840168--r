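## Raw-count processing per accession: library and gene filters, merging of
## technical libraries, median-of-ratios normalization and relative
## expression.  Stages run in the order
##   filter_genes -> filter_libraries -> merge_by_accession -> normalize ->
##   relative_expression.

#' Remove shallow sequencing libraries
#'
#' Drops libraries whose total count is strictly below `min_reads`; the
#' study default is 1e6 mapped reads, configurable down for small synthetic
#' libraries.  Accessions losing all of their libraries disappear from the
#' library map.
#'
#' @param counts a [count_matrix()].
#' @param min_reads minimum column total for a library to be kept.
#' @return Filtered [count_matrix()]; the removed library ids are attached
#'   as attribute `removed`.
#' @export
filter_libraries <- function(counts, min_reads = 1e6) {
  gk_assert(min_reads >= 0, "min_reads must be >= 0")
  totals <- colSums(counts$values)
  keep <- totals >= min_reads          # filter is strictly "less than"
  if (!any(keep))
    gk_stop("all libraries fall below min_reads", "glknet_all_filtered")
  removed <- colnames(counts$values)[!keep]
  if (length(removed) > 0)
    message(sprintf("filter_libraries: removed %d of %d libraries (< %g reads)",
                    length(removed), length(totals), min_reads))
  out <- count_matrix(counts$values[, keep, drop = FALSE],
                      counts$library_to_accession[keep])
  attr(out, "removed") <- removed
  out
}

#' Keep only nuclear protein-coding genes
#'
#' @param counts a [count_matrix()].
#' @param annotation a [genome_annotation()] covering every gene in `counts`.
#' @return Filtered [count_matrix()] (original gene order preserved).
#' @export
filter_genes <- function(counts, annotation) {
  ids <- rownames(counts$values)
  miss <- setdiff(ids, annotation$genes$gene_id)
  if (length(miss) > 0)
    gk_stop(paste("genes absent from annotation:", paste(miss, collapse = ", ")),
            "glknet_unannotated_gene")
  g <- annotation$genes[match(ids, annotation$genes$gene_id), ]
  keep <- g$biotype == "protein_coding" & g$compartment == "nuclear"
  count_matrix(counts$values[keep, , drop = FALSE], counts$library_to_accession)
}

#' Combine libraries of the same accession
#'
#' Sums counts (integer addition) across all libraries of each accession,
#' leaving one column per accession.
#'
#' @param counts a [count_matrix()].
#' @return A [count_matrix()] with one library (named by accession) per
#'   accession.
#' @export
merge_by_accession <- function(counts) {
  acc <- counts$library_to_accession
  accessions <- unique(unname(acc))
  merged <- vapply(accessions, function(a)
    rowSums(counts$values[, acc == a, drop = FALSE]),
    numeric(nrow(counts$values)))
  merged <- matrix(merged, nrow = nrow(counts$values),
                   dimnames = list(rownames(counts$values), accessions))
  count_matrix(merged, setNames(accessions, accessions))
}

#' Normalize counts by median-of-ratios size factors
#'
#' Size factors follow the median-of-ratios recipe: per gene, the geometric
#' mean across accessions forms a pseudo-reference (genes containing any
#' zero are excluded from it); each accession's size factor is the median
#' over reference genes of count / geometric mean.  Normalized expression is
#' `log2(count / size_factor + 1)` — a shifted-log variance flattening on
#' the same size factors a variance-stabilizing transformation would use
#' (see the methods vignette for why the full dispersion-trend fit is not
#' reproduced here).
#'
#' @param counts a [count_matrix()] with one column per accession (see
#'   [merge_by_accession()]).
#' @return An [expression_matrix()] on the `normalized` scale; size factors
#'   attached as attribute `size_factors`.
#' @export
normalize_counts <- function(counts) {
  v <- counts$values
  gk_assert(ncol(v) >= 2, "need at least 2 accessions to normalize")
  ref <- rowSums(v == 0) == 0
  if (!any(ref))
    gk_stop("no gene with all-positive counts; cannot form the median-of-ratios reference (consider a pseudo-reference fallback)",
            "glknet_no_reference_gene")
  geo <- exp(rowMeans(log(v[ref, , drop = FALSE])))
  sf <- apply(v[ref, , drop = FALSE] / geo, 2, median)
  norm <- log2(sweep(v, 2, sf, `/`) + 1)
  out <- expression_matrix(norm, "normalized")
  attr(out, "size_factors") <- sf
  out
}

#' Center expression per gene
#'
#' Subtracts each gene's mean across accessions, yielding relative
#' expression.
#'
#' @param expr an [expression_matrix()] on the `normalized` scale.
#' @return An [expression_matrix()] on the `relative` scale.
#' @export
relative_expression <- function(expr) {
  gk_assert(inherits(expr, "expression_matrix"), "expr must be an expression_matrix")
  if (expr$scale == "relative")
    gk_stop("expression is already relative (double centering)",
            "glknet_already_relative")
  expression_matrix(expr$values - rowMeans(expr$values), "relative")
}
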