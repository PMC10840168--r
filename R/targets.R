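## Candidate direct targets of a focal transcription factor, defined from
## ranked binding sites and a gene annotation.

#' Select the strongest binding sites
#'
#' Optionally applies a site-level FDR bound, then sorts by ascending FDR
#' (ties broken by descending score, then by chromosome and start) and keeps
#' the first `n`.
#'
#' @param sites a [binding_sites()] data.frame.
#' @param n number of sites to keep (all if fewer pass).
#' @param max_fdr optional FDR bound applied before the top-n cut (strict
#'   `<`); the study default is `7.2e-11`.
#' @return The selected sites, in sorted order.
#' @export
select_top_sites <- function(sites, n = 100, max_fdr = NULL) {
  gk_assert(nrow(sites) > 0, "empty site list", "glknet_empty_sites")
  gk_assert(n >= 1, "n must be >= 1")
  if (!is.null(max_fdr)) sites <- sites[sites$fdr < max_fdr, , drop = FALSE]
  ord <- order(sites$fdr, -sites$score, sites$chrom, sites$start)
  out <- sites[ord, , drop = FALSE]
  out <- head(out, n)
  rownames(out) <- NULL
  out
}

#' Assign binding sites to candidate target genes
#'
#' A gene is a candidate target when any site overlaps (by at least 1 bp)
#' the window from `upstream` bp before the gene start to `downstream` bp
#' after the gene end.  The window is symmetric and strand-agnostic: it
#' covers the upstream, genic and downstream region on both sides.  Only
#' nuclear protein-coding genes are eligible.
#'
#' @param sites a [binding_sites()] data.frame (typically the output of
#'   [select_top_sites()]).
#' @param annotation a [genome_annotation()].
#' @param upstream,downstream window extension in bp (defaults 1000/1000).
#' @return Character vector of candidate target gene ids (deduplicated,
#'   annotation order).
#' @export
assign_sites_to_genes <- function(sites, annotation, upstream = 1000,
                                  downstream = 1000) {
  gk_assert(upstream >= 0 && downstream >= 0,
            "upstream/downstream must be >= 0")
  genes <- annotation$genes
  eligible <- genes$biotype == "protein_coding" & genes$compartment == "nuclear"
  genes <- genes[eligible, , drop = FALSE]
  unknown <- setdiff(unique(sites$chrom), unique(annotation$genes$chrom))
  if (length(unknown) > 0) {
    warning("sites on chromosomes absent from the annotation skipped: ",
            paste(unknown, collapse = ", "))
    sites <- sites[!(sites$chrom %in% unknown), , drop = FALSE]
  }
  if (nrow(sites) == 0 || nrow(genes) == 0) return(character())
  ## windows in 0-based half-open: [start - upstream, end + downstream);
  ## converted to 1-based closed for IRanges overlap machinery
  win <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(start = pmax(genes$start - upstream, 0) + 1,
                     end = genes$end + downstream)
  )
  sr <- GenomicRanges::GRanges(
    sites$chrom, IRanges::IRanges(start = sites$start + 1, end = sites$end)
  )
  hits <- GenomicRanges::findOverlaps(sr, win, minoverlap = 1L)
  genes$gene_id[sort(unique(S4Vectors::subjectHits(hits)))]
}
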