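# Shared fixtures: a fast small-study configuration, the expression
# pipeline shorthand, and a hand-built network for graph-traversal tests.

small_config <- function(seed = 1, ...) {
  args <- list(n_accessions = 60, group_sizes = c(24, 36), n_genes = 80,
               n_target_genes = 20, n_network_genes = 12, n_snps = 60,
               n_causal_snps = 8, n_stop_gain = 2, seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(generator_config, args)
}

## counts -> merged per-accession normalized expression, quietly
bundle_expression <- function(bundle, min_reads = bundle$truth$min_reads) {
  cm <- filter_genes(bundle$counts, bundle$annotation)
  cm <- suppressMessages(filter_libraries(cm, min_reads))
  normalize_counts(merge_by_accession(cm))
}

## a ggm_network built directly from an edge list (all listed edges get the
## given p, everything else p = 1), for traversal/comparison unit tests
fake_network <- function(genes, edges, p = 1e-4) {
  n <- length(genes)
  pcor <- diag(n)
  pv <- matrix(1, n, n)
  dimnames(pcor) <- dimnames(pv) <- list(genes, genes)
  diag(pv) <- NA_real_
  if (nrow(edges) > 0) {
    i <- match(edges$gene_i, genes)
    j <- match(edges$gene_j, genes)
    pcor[cbind(i, j)] <- pcor[cbind(j, i)] <- edges$pcor
    pv[cbind(i, j)] <- pv[cbind(j, i)] <- if (length(p) == 1)
      rep(p, nrow(edges)) else p
  }
  structure(list(genes = genes, pcor = pcor, lambda = 0, kappa = 100,
                 p_values = pv, alpha = 0.05,
                 edges = edges), class = "ggm_network")
}

expect_error_class <- function(expr, class) {
  expect_error(expr, class = class)
}
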