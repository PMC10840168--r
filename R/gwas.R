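## Allelic association between two accession groups, plus a codon-level
## variant-consequence caller for the toy annotation (standing in for a
## web-service effect predictor) and the filter cascade
##   p < 1e-10  ->  frequency > 25% in either group  ->  exonic  ->  impact.

#' Allelic chi-square association test
#'
#' Per variant, builds the 2x2 allele-count table (alt/ref x group; a
#' heterozygous dosage contributes one allele of each kind, missing dosages
#' are excluded) and computes the Pearson chi-square statistic without
#' continuity correction, with p from the 1-df chi-square distribution.
#' Monomorphic variants get `chi2 = 0, p = 1`; variants with all genotypes
#' missing in either group get `p = NA`.
#'
#' @param genotypes a [genotype_matrix()].
#' @param groups an accession [grouping()].
#' @param group_a,group_b cluster ids to contrast.
#' @return data.frame per variant: `id`, `chrom`, `pos`, `ref`, `alt`,
#'   `alt_a`, `ref_a`, `alt_b`, `ref_b` (allele counts), `chi2`, `p_value`,
#'   `freq_a`, `freq_b`.
#' @export
allelic_chisq <- function(genotypes, groups, group_a, group_b) {
  a_ids <- intersect(group_members(groups, group_a), colnames(genotypes$dosages))
  b_ids <- intersect(group_members(groups, group_b), colnames(genotypes$dosages))
  gk_assert(length(a_ids) > 0 && length(b_ids) > 0, "both groups must be non-empty")
  counts_for <- function(ids) {
    d <- genotypes$dosages[, ids, drop = FALSE]
    nn <- rowSums(!is.na(d))
    alt <- rowSums(d, na.rm = TRUE)
    cbind(alt = alt, ref = 2 * nn - alt)
  }
  ca <- counts_for(a_ids)
  cb <- counts_for(b_ids)
  a <- ca[, "alt"]; b <- cb[, "alt"]; c_ <- ca[, "ref"]; d <- cb[, "ref"]
  n <- a + b + c_ + d
  chi2 <- n * (a * d - b * c_)^2 /
    pmax((a + b) * (c_ + d) * (a + c_) * (b + d), 1)
  mono <- (a + b == 0) | (c_ + d == 0)
  chi2[mono] <- 0
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  p[mono] <- 1
  empty <- (a + c_ == 0) | (b + d == 0)
  chi2[empty] <- NA_real_
  p[empty] <- NA_real_
  data.frame(
    genotypes$variants[, c("id", "chrom", "pos", "ref", "alt")],
    alt_a = a, ref_a = c_, alt_b = b, ref_b = d,
    chi2 = chi2, p_value = p,
    freq_a = ifelse(a + c_ > 0, a / (a + c_), NA_real_),
    freq_b = ifelse(b + d > 0, b / (b + d), NA_real_),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Alternate-allele frequency within one group
#'
#' @param genotypes a [genotype_matrix()].
#' @param groups an accession [grouping()].
#' @param group_id cluster id.
#' @return Named numeric vector (per variant): alt-allele count over twice
#'   the non-missing accession count.
#' @export
group_allele_frequency <- function(genotypes, groups, group_id) {
  ids <- intersect(group_members(groups, group_id), colnames(genotypes$dosages))
  gk_assert(length(ids) > 0, "group has no genotyped accessions")
  d <- genotypes$dosages[, ids, drop = FALSE]
  nn <- rowSums(!is.na(d))
  setNames(ifelse(nn > 0, rowSums(d, na.rm = TRUE) / (2 * nn), NA_real_),
           genotypes$variants$id)
}

GK_CODE <- Biostrings::GENETIC_CODE

#' Predict the protein consequence of a single-nucleotide variant
#'
#' Locates the variant in the annotation: outside all genes it is
#' `noncoding` (MODIFIER); inside a gene but outside the CDS, `other`
#' (MODIFIER).  Within a CDS, the affected codon is spliced from the genome
#' (reverse-complemented for minus-strand genes), the alternate base is
#' substituted and both codons translated with the standard genetic code:
#' a new stop codon where the reference codon was not one is `stop_gained`
#' (HIGH); any other amino-acid change is `missense` (MODERATE); a silent
#' change is `synonymous` (LOW).
#'
#' @param variant list or one-row data.frame with `chrom`, `pos` (1-based),
#'   `ref`, `alt` (single bases).
#' @param annotation a [genome_annotation()] carrying chromosome sequences.
#' @return List with `consequence` (one of `stop_gained`, `missense`,
#'   `synonymous`, `noncoding`, `other`), `impact` (`HIGH`, `MODERATE`,
#'   `LOW`, `MODIFIER`) and `in_exon` (inside any CDS segment).
#' @export
predict_consequence <- function(variant, annotation) {
  gk_assert(!is.null(annotation$genome), "annotation carries no sequence")
  chrom <- as.character(variant$chrom)
  pos <- as.integer(variant$pos)         # 1-based
  ref <- toupper(as.character(variant$ref))
  alt <- toupper(as.character(variant$alt))
  gk_assert(nchar(ref) == 1 && nchar(alt) == 1, "SNV required (single bases)")
  pos0 <- pos - 1L
  seq <- annotation$genome[[chrom]]
  gk_assert(!is.null(seq), paste("chromosome absent from genome:", chrom))
  genome_base <- substr(seq, pos, pos)
  if (genome_base != ref)
    gk_stop(sprintf("ref allele %s disagrees with annotated base %s at %s:%d",
                    ref, genome_base, chrom, pos), "glknet_ref_mismatch")
  genes <- annotation$genes
  in_gene <- genes$chrom == chrom & pos0 >= genes$start & pos0 < genes$end
  cds <- annotation$cds
  hit_cds <- cds$chrom == chrom & pos0 >= cds$start & pos0 < cds$end
  in_exon <- any(hit_cds)
  if (!any(in_gene))
    return(list(consequence = "noncoding", impact = "MODIFIER", in_exon = in_exon))
  if (!in_exon)
    return(list(consequence = "other", impact = "MODIFIER", in_exon = FALSE))
  ## translate the affected codon of the first CDS hit
  gid <- cds$gene_id[which(hit_cds)[1]]
  strand <- genes$strand[genes$gene_id == gid]
  gcds <- cds[cds$gene_id == gid, , drop = FALSE]
  gcds <- gcds[order(gcds$start), , drop = FALSE]
  ## offset of the variant within the spliced coding sequence
  if (strand == "+") {
    prior <- sum(pmax(pmin(gcds$end, pos0) - gcds$start, 0))
    coding_off <- prior                        # 0-based; pos0 not yet counted
  } else {
    after <- sum(pmax(gcds$end - pmax(gcds$start, pos0 + 1L), 0))
    coding_off <- after
  }
  cseq <- coding_sequence(annotation, gid)
  codon_idx <- coding_off %/% 3L
  cp <- coding_off %% 3L + 1L
  codon <- substr(cseq, 3L * codon_idx + 1L, 3L * codon_idx + 3L)
  alt_coding <- if (strand == "+") alt else chartr("ACGT", "TGCA", alt)
  mutated <- codon
  substr(mutated, cp, cp) <- alt_coding
  aa_old <- GK_CODE[[codon]]
  aa_new <- GK_CODE[[mutated]]
  if (aa_new == "*" && aa_old != "*")
    list(consequence = "stop_gained", impact = "HIGH", in_exon = TRUE)
  else if (aa_new != aa_old)
    list(consequence = "missense", impact = "MODERATE", in_exon = TRUE)
  else
    list(consequence = "synonymous", impact = "LOW", in_exon = TRUE)
}

#' Annotate an association table with predicted consequences
#'
#' Runs [predict_consequence()] on every SNV row of an association table
#' (non-SNV records, e.g. short indels, are labeled `other`/`MODIFIER`).
#'
#' @param assoc output of [allelic_chisq()].
#' @param annotation a [genome_annotation()] with sequences.
#' @return `assoc` with added columns `consequence`, `impact`, `in_exon`.
#' @export
annotate_consequences <- function(assoc, annotation) {
  res <- lapply(seq_len(nrow(assoc)), function(i) {
    v <- assoc[i, ]
    if (nchar(v$ref) != 1 || nchar(v$alt) != 1)
      return(list(consequence = "other", impact = "MODIFIER", in_exon = FALSE))
    predict_consequence(v, annotation)
  })
  assoc$consequence <- vapply(res, `[[`, "", "consequence")
  assoc$impact <- vapply(res, `[[`, "", "impact")
  assoc$in_exon <- vapply(res, `[[`, NA, "in_exon")
  assoc
}

#' Filter associated variants down to high-impact candidates
#'
#' Applies the study's cascade with strict bounds: association
#' `p < p_threshold`, alternate-allele frequency `> freq_min` in at least
#' one of the two groups, exonic localization, then restriction to the
#' requested impact classes.  The counts surviving each stage are attached
#' as attribute `cascade`.
#'
#' @param assoc output of [annotate_consequences()].
#' @param p_threshold association p bound (default 1e-10, strict `<`).
#' @param freq_min frequency bound (default 0.25, strict `>`).
#' @param impact_in impact classes to keep (default `"HIGH"`).
#' @return Filtered data.frame with a logical `passes_filters` column on the
#'   input rows available via attribute `full` of the cascade.
#' @export
filter_variants <- function(assoc, p_threshold = 1e-10, freq_min = 0.25,
                            impact_in = "HIGH") {
  gk_assert(all(c("consequence", "impact", "in_exon") %in% names(assoc)),
            "assoc must be annotated (see annotate_consequences)")
  p_ok <- !is.na(assoc$p_value) & assoc$p_value < p_threshold
  f_ok <- (!is.na(assoc$freq_a) & assoc$freq_a > freq_min) |
    (!is.na(assoc$freq_b) & assoc$freq_b > freq_min)
  e_ok <- assoc$in_exon
  pass <- p_ok & f_ok & e_ok
  keep <- pass & assoc$impact %in% impact_in
  out <- assoc[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "cascade") <- c(
    total = nrow(assoc),
    p_filter = sum(p_ok),
    p_freq_exon = sum(pass),
    impact = sum(keep),
    stop_gained = sum(keep & assoc$consequence == "stop_gained")
  )
  out
}
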