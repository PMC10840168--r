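## Focal-gene neighborhood extraction and between-group comparison of edge
## strengths: partial-correlation graphs are undirected, so the "steps
## upstream" expansion is a breadth-first traversal.

#' Extract the focal-gene neighborhood of a network
#'
#' Breadth-first expansion over edges with `p < alpha`: level 0 is the focal
#' gene, each further level adds genes significantly linked to any gene
#' already selected, up to `steps` expansions (or until no new gene joins).
#'
#' @param network a `ggm_network` (see [build_network()]).
#' @param focal focal gene id.
#' @param alpha edge significance bound (default 0.01).
#' @param steps number of expansions (default 5).
#' @return Character vector of selected gene ids, focal included, in
#'   panel order.
#' @export
extract_neighborhood <- function(network, focal, alpha = 0.01, steps = 5) {
  gk_assert(focal %in% network$genes, paste("focal gene absent:", focal))
  gk_assert(steps >= 0, "steps must be >= 0")
  adj <- !is.na(network$p_values) & network$p_values < alpha
  selected <- network$genes == focal
  for (s in seq_len(steps)) {
    frontier <- (colSums(adj[selected, , drop = FALSE]) > 0) & !selected
    if (!any(frontier)) break
    selected <- selected | frontier
  }
  network$genes[selected]
}

#' Compare edge strengths between two group networks
#'
#' For every gene pair within `genes` whose edge is significant
#' (`p < alpha`) in the *reference* network, pairs the partial correlation
#' in the reference with the one in the alternate network.
#' `delta = reference - alternate`; an edge is flagged when
#' `|delta| > delta_threshold` (strict).  Edges significant only in the
#' alternate network are deliberately not reported.
#'
#' @param reference,alternate two `ggm_network`s over the same gene panel.
#' @param genes gene ids to restrict to (e.g. an [extract_neighborhood()]
#'   result); default: the whole shared panel.
#' @param alpha significance bound evaluated in the reference network
#'   (default 0.01).
#' @param delta_threshold flagging bound on |delta| (default 0.2).
#' @return data.frame sorted by descending |delta| (ties by gene pair):
#'   `gene_i`, `gene_j`, `strength_ref`, `strength_alt`, `delta`, `flagged`.
#' @export
compare_edge_strengths <- function(reference, alternate, genes = NULL,
                                   alpha = 0.01, delta_threshold = 0.2) {
  gk_assert(identical(reference$genes, alternate$genes),
            "networks must be built over the same gene panel")
  if (is.null(genes)) genes <- reference$genes
  miss <- setdiff(genes, reference$genes)
  if (length(miss) > 0)
    gk_stop(paste("genes missing from the networks:",
                  paste(miss, collapse = ", ")), "glknet_missing_gene")
  idx <- match(genes, reference$genes)
  pv <- reference$p_values[idx, idx, drop = FALSE]
  pr <- reference$pcor[idx, idx, drop = FALSE]
  pa <- alternate$pcor[idx, idx, drop = FALSE]
  sel <- which(upper.tri(pv) & !is.na(pv) & pv < alpha, arr.ind = TRUE)
  out <- data.frame(
    gene_i = genes[sel[, 1]],
    gene_j = genes[sel[, 2]],
    strength_ref = pr[sel],
    strength_alt = pa[sel],
    stringsAsFactors = FALSE
  )
  out$delta <- out$strength_ref - out$strength_alt
  out$flagged <- abs(out$delta) > delta_threshold
  out <- out[order(-abs(out$delta), out$gene_i, out$gene_j), , drop = FALSE]
  rownames(out) <- NULL
  out
}
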