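# Allelic association, group frequencies, consequence calling and the
# candidate filter cascade.

mk_gt <- function(dosages, chrom = "c1", pos = seq_len(nrow(dosages)),
                  ref = "A", alt = "C") {
  genotype_matrix(data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt),
                  dosages)
}

test_that("allelic chi-square matches the closed-form 2x2 Pearson statistic", {
  ## group A: 40 alt / 60 ref alleles; group B: 70 alt / 30 ref
  dos <- matrix(c(rep(1, 40), rep(0, 10),       # A: 40 het, 10 homref
                  rep(2, 35), rep(0, 15)),      # B: 35 homalt, 15 homref
                nrow = 1)
  colnames(dos) <- sprintf("a%03d", 1:100)
  g <- grouping(setNames(rep(1:2, each = 50), colnames(dos)))
  res <- allelic_chisq(mk_gt(dos), g, 1, 2)
  chi_exp <- 200 * (40 * 30 - 60 * 70)^2 / (100 * 100 * 110 * 90)
  expect_equal(res$chi2, chi_exp, tolerance = 1e-12)
  expect_equal(res$p_value, pchisq(chi_exp, 1, lower.tail = FALSE))
  expect_equal(res$freq_a, 0.4)
  expect_equal(res$freq_b, 0.7)
})

test_that("null and monomorphic variants are handled", {
  dos <- rbind(rep(c(0, 1, 2), 4),      # identical pattern in both groups
               rep(0, 12),              # monomorphic ref
               rep(2, 12))              # monomorphic alt
  colnames(dos) <- sprintf("a%02d", 1:12)
  g <- grouping(setNames(rep(1:2, each = 6), colnames(dos)))
  res <- allelic_chisq(mk_gt(dos), g, 1, 2)
  expect_equal(res$chi2[1], 0)
  expect_equal(res$p_value, c(1, 1, 1))
})

test_that("chi-square equals an independent contingency-table computation", {
  set.seed(29)
  n <- 80
  dos <- matrix(sample(c(0L, 1L, 2L, NA), 100 * n, TRUE,
                       prob = c(.4, .2, .35, .05)), 100, n)
  colnames(dos) <- sprintf("a%03d", seq_len(n))
  g <- grouping(setNames(rep(1:2, c(30, 50)), colnames(dos)))
  res <- allelic_chisq(mk_gt(dos), g, 1, 2)
  for (i in seq_len(100)) {
    tab <- matrix(c(res$alt_a[i], res$ref_a[i], res$alt_b[i], res$ref_b[i]), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      expect_equal(res$p_value[i], 1)
    } else {
      oracle <- suppressWarnings(chisq.test(tab, correct = FALSE))
      expect_equal(res$chi2[i], unname(oracle$statistic), tolerance = 1e-10)
      expect_equal(res$p_value[i], oracle$p.value, tolerance = 1e-10)
    }
  }
})

test_that("group allele frequency excludes missing genotypes", {
  dos <- matrix(c(0, 1, 2, 0, 1, NA), nrow = 2, byrow = TRUE)
  colnames(dos) <- c("a1", "a2", "a3")
  g <- grouping(setNames(rep(1, 3), colnames(dos)), k = 1)
  f <- group_allele_frequency(mk_gt(dos, pos = 1:2), g, 1)
  expect_equal(unname(f), c(3 / 6, 1 / 4))
  dos0 <- matrix(0, 1, 3, dimnames = list(NULL, c("a1", "a2", "a3")))
  expect_equal(unname(group_allele_frequency(mk_gt(dos0), g, 1)), 0)
})

test_that("codon-level consequences follow the genetic code", {
  ## plus-strand gene, CDS = CAG CTT GAT
  seqs <- c(c1 = paste0(strrep("A", 10), "CAGCTTGAT", strrep("A", 10)))
  ann <- genome_annotation(
    data.frame(gene_id = "gX", chrom = "c1", start = 8L, end = 22L,
               strand = "+", biotype = "protein_coding",
               compartment = "nuclear"),
    data.frame(gene_id = "gX", chrom = "c1", start = 10L, end = 19L,
               phase = 0L),
    seqs)
  stop_g <- predict_consequence(list(chrom = "c1", pos = 11, ref = "C",
                                     alt = "T"), ann)  # CAG -> TAG
  expect_equal(stop_g$consequence, "stop_gained")
  expect_equal(stop_g$impact, "HIGH")
  syn <- predict_consequence(list(chrom = "c1", pos = 16, ref = "T",
                                  alt = "C"), ann)     # CTT -> CTC
  expect_equal(syn$consequence, "synonymous")
  expect_equal(syn$impact, "LOW")
  mis <- predict_consequence(list(chrom = "c1", pos = 18, ref = "A",
                                  alt = "C"), ann)     # GAT -> GCT
  expect_equal(mis$consequence, "missense")
  expect_equal(mis$impact, "MODERATE")
  ## outside any gene / inside gene but outside CDS
  nc <- predict_consequence(list(chrom = "c1", pos = 2, ref = "A",
                                 alt = "G"), ann)
  expect_equal(nc$consequence, "noncoding")
  expect_false(nc$in_exon)
  intr <- predict_consequence(list(chrom = "c1", pos = 9, ref = "A",
                                   alt = "G"), ann)
  expect_equal(intr$consequence, "other")
  ## data integrity: wrong ref base
  expect_error(predict_consequence(list(chrom = "c1", pos = 11, ref = "G",
                                        alt = "T"), ann),
               class = "glknet_ref_mismatch")
})

test_that("consequences agree with full-CDS translation on both strands", {
  for (strand in c("+", "-")) {
    set.seed(9)
    chrom_seq <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
    ann <- genome_annotation(
      data.frame(gene_id = "gX", chrom = "c1", start = 10L, end = 30L,
                 strand = strand, biotype = "protein_coding",
                 compartment = "nuclear"),
      data.frame(gene_id = "gX", chrom = "c1", start = 15L, end = 24L,
                 phase = 0L),
      c(c1 = chrom_seq))
    translate_cds <- function(s) {
      x <- substr(s, 16, 24)
      if (strand == "-")
        x <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
      as.character(Biostrings::translate(Biostrings::DNAString(x),
                                         no.init.codon = TRUE))
    }
    p_old <- translate_cds(chrom_seq)
    for (pos0 in 15:23) {
      ref <- substr(chrom_seq, pos0 + 1, pos0 + 1)
      for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
        got <- predict_consequence(list(chrom = "c1", pos = pos0 + 1,
                                        ref = ref, alt = alt), ann)
        mut <- chrom_seq
        substr(mut, pos0 + 1, pos0 + 1) <- alt
        p_new <- translate_cds(mut)
        new_stop <- any(vapply(seq_len(nchar(p_new)), function(i)
          substr(p_new, i, i) == "*" && substr(p_old, i, i) != "*", NA))
        want <- if (new_stop) "stop_gained"
        else if (p_new != p_old) "missense" else "synonymous"
        expect_equal(got$consequence, want,
                     label = sprintf("strand %s pos %d %s>%s", strand,
                                     pos0, ref, alt))
      }
    }
  }
})

test_that("filter cascade applies strict bounds", {
  assoc <- data.frame(
    id = sprintf("v%d", 1:4), chrom = "c1", pos = 1:4, ref = "A", alt = "C",
    alt_a = 0, ref_a = 0, alt_b = 0, ref_b = 0,
    chi2 = 50, p_value = c(1e-10, 1e-11, 1e-11, 1e-11),
    freq_a = c(0.5, 0.25, 0.5, 0.5), freq_b = c(0.5, 0.10, 0.5, 0.5),
    consequence = c("stop_gained", "stop_gained", "stop_gained", "missense"),
    impact = c("HIGH", "HIGH", "HIGH", "MODERATE"),
    in_exon = TRUE, stringsAsFactors = FALSE)
  out <- filter_variants(assoc)
  expect_equal(out$id, "v3")          # v1: p not < 1e-10; v2: freq not > 0.25
  casc <- attr(out, "cascade")
  expect_true(all(diff(unname(casc[c("total", "p_filter", "p_freq_exon",
                                     "impact")])) <= 0))
  out2 <- filter_variants(assoc, impact_in = c("HIGH", "MODERATE"))
  expect_setequal(out2$id, c("v3", "v4"))
})

test_that("planted stop-gain causal variants are exactly the HIGH candidates", {
  ## study-scale groups: the 1e-10 association bound needs n = 200
  b <- generate_dataset(generator_config(seed = 33))
  gr <- grouping(b$truth$accession_groups)
  assoc <- allelic_chisq(b$genotypes, gr, 1, 2)
  assoc <- annotate_consequences(assoc, b$annotation)
  cand <- filter_variants(assoc, p_threshold = 1e-10, freq_min = 0.25,
                          impact_in = "HIGH")
  expect_setequal(cand$id, b$truth$stop_gain_variants)
  expect_true(all(cand$consequence == "stop_gained"))
})
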