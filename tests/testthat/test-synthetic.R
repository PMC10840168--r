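# Generator: determinism, null planting, planted allele-frequency gaps,
# precision-matrix construction, and file round-trips.

test_that("generation is byte-identical given the same seed", {
  b1 <- generate_dataset(small_config(seed = 5))
  b2 <- generate_dataset(small_config(seed = 5))
  expect_identical(b1, b2)
  b3 <- generate_dataset(small_config(seed = 6))
  expect_false(identical(b1$counts$values, b3$counts$values))
})

test_that("null planting empties the truth record and downstream signals", {
  b <- generate_dataset(small_config(seed = 2, de_log2fc = 0,
                                     diff_edge_delta = 0, srad_sd_ratio = 1))
  expect_equal(nrow(b$truth$de_genes), 0)
  expect_equal(nrow(b$truth$differential_edges), 0)
  ## groups are expression-indistinguishable: DE at the study thresholds
  ## finds nothing
  norm <- bundle_expression(b)
  de <- differential_expression(norm, grouping(b$truth$accession_groups),
                                1, 2)
  expect_equal(sum(de$significant), 0)
})

test_that("invalid configurations are rejected with the offending field", {
  expect_error(generator_config(n_accessions = 10, group_sizes = c(4, 4)),
               "group_sizes")
  expect_error(generator_config(n_causal_snps = 1000, n_snps = 10),
               "n_causal_snps")
  expect_error(generator_config(n_genes = 30, n_target_genes = 25,
                                n_network_genes = 10), "n_target_genes")
  expect_error(generator_config(network_pcor = 1.2), "network_pcor")
  expect_error(generator_config(nb_dispersion = 0), "nb_dispersion")
})

test_that("planted causal variants show the promised frequency gap, nulls do not", {
  b <- generate_dataset(generator_config(n_accessions = 200,
                                         group_sizes = c(80, 120),
                                         n_snps = 500, n_causal_snps = 20,
                                         seed = 11))
  expect_equal(dim(b$genotypes$dosages), c(500, 200))
  gr <- grouping(b$truth$accession_groups)
  f1 <- group_allele_frequency(b$genotypes, gr, 1)
  f2 <- group_allele_frequency(b$genotypes, gr, 2)
  gap <- abs(f1 - f2)
  causal <- b$truth$causal_snps$id
  expect_length(causal, 20)
  expect_true(all(gap[causal] >= 0.4))
  expect_true(all(gap[setdiff(names(gap), causal)] < 0.4))
})

test_that("precision_from_edges realizes requested partial correlations exactly", {
  genes <- c("a", "b", "c")
  ## empty graph -> identity
  K0 <- precision_from_edges(genes, data.frame(gene_i = character(),
                                               gene_j = character(),
                                               pcor = numeric()))
  expect_equal(unname(K0), diag(3))
  ## single edge: invert and re-standardize as an independent oracle
  K <- precision_from_edges(genes, data.frame(gene_i = "a", gene_j = "b",
                                              pcor = 0.5))
  sigma <- solve(K)
  oracle_pcor <- -stats::cov2cor(solve(stats::cov2cor(sigma)))
  expect_equal(oracle_pcor["a", "b"], 0.5, tolerance = 1e-10)
  expect_equal(oracle_pcor["a", "c"], 0, tolerance = 1e-10)
  expect_equal(oracle_pcor["b", "c"], 0, tolerance = 1e-10)
  ## infeasible chain: explicit error, never a non-PD return
  chain <- data.frame(gene_i = c("a", "b", "c"), gene_j = c("b", "c", "d"),
                      pcor = 0.99)
  res <- tryCatch(precision_from_edges(c("a", "b", "c", "d"), chain),
                  glknet_infeasible_edges = function(e) "infeasible")
  if (is.matrix(res)) {
    expect_gt(min(eigen(res, only.values = TRUE)$values), 0)
  } else {
    expect_identical(res, "infeasible")
  }
})

test_that("sampling from a planted precision matrix recovers the pcors", {
  genes <- sprintf("g%02d", 1:10)
  edges <- data.frame(gene_i = genes[c(1, 3, 5)], gene_j = genes[c(2, 4, 6)],
                      pcor = c(0.5, 0.3, -0.4))
  K <- precision_from_edges(genes, edges)
  set.seed(31)
  x <- t(sample_network_expression(K, 2000))
  pc <- partial_correlations(x, shrinkage_intensity(x))
  est <- pc[cbind(match(edges$gene_i, genes), match(edges$gene_j, genes))]
  expect_lt(mean(abs(est - edges$pcor)), 0.05)
})

test_that("bundles round-trip through the file readers", {
  b <- generate_dataset(small_config(seed = 3))
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  r <- read_bundle(dir)
  expect_identical(r$counts$values, b$counts$values)
  expect_identical(r$counts$library_to_accession, b$counts$library_to_accession)
  expect_identical(r$genotypes$dosages, b$genotypes$dosages)
  expect_equal(r$genotypes$variants$pos, b$genotypes$variants$pos)
  expect_equal(r$annotation$genes[, c("gene_id", "chrom", "start", "end",
                                      "strand", "biotype", "compartment")],
               b$annotation$genes[, c("gene_id", "chrom", "start", "end",
                                      "strand", "biotype", "compartment")])
  expect_identical(r$annotation$genome, b$annotation$genome)
  expect_equal(r$sites$start, b$sites$start)
  expect_equal(r$sites$fdr, b$sites$fdr, tolerance = 1e-12)
  expect_equal(as.numeric(as.matrix(r$climate[, -(1:2)])),
               as.numeric(as.matrix(b$climate[, -(1:2)])), tolerance = 1e-9)
  expect_equal(r$photosynthesis$value, b$photosynthesis$value,
               tolerance = 1e-9)
  expect_identical(unlist(r$truth$accession_groups),
                   b$truth$accession_groups)
  expect_identical(r$network_panel, b$truth$network_genes)
})
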