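## Core containers.  All genomic coordinates held in these objects are
## 0-based half-open [start, end); conversion to the 1-based conventions of
## GFF3 and VCF happens only at the file boundary (io.R).

#' Genome annotation container
#'
#' Holds gene models for a (toy or real) genome: one row per gene plus the
#' CDS segments needed by the variant-consequence caller, and optionally the
#' chromosome sequences themselves.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand` (`"+"`/`"-"`), `biotype`
#'   (e.g. `"protein_coding"`), `compartment` (`"nuclear"` or `"organellar"`).
#' @param cds data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `phase`; every segment must lie within its gene's interval.
#' @param genome optional named character vector of chromosome sequences
#'   (A/C/G/T), required by [predict_consequence()].
#' @return An object of class `genome_annotation`.
#' @export
genome_annotation <- function(genes, cds = NULL, genome = NULL) {
  need <- c("gene_id", "chrom", "start", "end", "strand", "biotype", "compartment")
  gk_assert(all(need %in% names(genes)),
            paste("genes is missing columns:",
                  paste(setdiff(need, names(genes)), collapse = ", ")))
  gk_assert(!anyDuplicated(genes$gene_id), "duplicated gene_id in annotation")
  gk_assert(all(genes$start < genes$end), "gene intervals need start < end")
  gk_assert(all(genes$compartment %in% c("nuclear", "organellar")),
            "compartment must be 'nuclear' or 'organellar'")
  if (is.null(cds)) {
    cds <- data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(), phase = integer())
  } else {
    gk_assert(all(cds$gene_id %in% genes$gene_id), "CDS for unknown gene_id")
    gi <- match(cds$gene_id, genes$gene_id)
    gk_assert(all(cds$start >= genes$start[gi] & cds$end <= genes$end[gi]),
              "CDS segment outside its gene interval")
    gk_assert(all(cds$start < cds$end), "CDS intervals need start < end")
  }
  structure(list(genes = genes, cds = cds, genome = genome),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("<genome_annotation> %d genes, %d CDS segments, %d chromosomes%s\n",
              nrow(x$genes), nrow(x$cds),
              length(unique(x$genes$chrom)),
              if (is.null(x$genome)) " (no sequence)" else " (+sequence)"))
  invisible(x)
}

#' Binding-site table constructor
#'
#' @param chrom,start,end site coordinates (0-based half-open).
#' @param score site score (e.g. peak enrichment); larger is stronger.
#' @param fdr site-level false-discovery rate in \[0, 1\].
#' @return data.frame of class `binding_sites`.
#' @export
binding_sites <- function(chrom, start, end, score, fdr) {
  gk_assert(all(start < end), "sites need start < end")
  gk_assert(all(fdr >= 0 & fdr <= 1), "site fdr must lie in [0, 1]")
  structure(data.frame(chrom = chrom, start = start, end = end,
                       score = score, fdr = fdr,
                       stringsAsFactors = FALSE),
            class = c("binding_sites", "data.frame"))
}

#' Raw count matrix with a library-to-accession map
#'
#' @param values non-negative integer matrix, genes x libraries, with
#'   rownames (gene ids) and colnames (library ids).
#' @param library_to_accession named character vector mapping every library
#'   id to its accession id.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(values, library_to_accession) {
  gk_assert(is.matrix(values) && !is.null(rownames(values)) &&
              !is.null(colnames(values)), "values must be a named matrix")
  gk_assert(all(values >= 0), "counts must be non-negative")
  gk_assert(all(colnames(values) %in% names(library_to_accession)),
            "every library must map to an accession")
  lib2acc <- library_to_accession[colnames(values)]
  structure(list(values = values, library_to_accession = lib2acc),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes x %d libraries (%d accessions)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$library_to_accession))))
  invisible(x)
}

#' Normalized or relative expression matrix
#'
#' @param values numeric matrix, genes x accessions, with dimnames.
#' @param scale `"normalized"` (log2 median-of-ratios scale) or `"relative"`
#'   (row-centered).
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, scale = c("normalized", "relative")) {
  scale <- match.arg(scale)
  gk_assert(is.matrix(values) && !is.null(rownames(values)) &&
              !is.null(colnames(values)), "values must be a named matrix")
  if (scale == "relative")
    gk_assert(all(abs(rowMeans(values)) < 1e-9),
              "relative-scale rows must have mean 0")
  structure(list(values = values, scale = scale), class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix:%s> %d genes x %d accessions\n",
              x$scale, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Biallelic genotype matrix
#'
#' @param variants data.frame with columns `chrom`, `pos` (1-based, VCF
#'   convention), `ref`, `alt`; one row per biallelic variant.
#' @param dosages matrix variants x accessions of alternate-allele dosages
#'   in \{0, 1, 2, NA\}; colnames are accession ids.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(variants, dosages) {
  need <- c("chrom", "pos", "ref", "alt")
  gk_assert(all(need %in% names(variants)), "variants needs chrom/pos/ref/alt")
  gk_assert(nrow(variants) == nrow(dosages), "variants/dosages row mismatch")
  gk_assert(!is.null(colnames(dosages)), "dosages needs accession colnames")
  gk_assert(all(variants$ref != variants$alt), "ref and alt must differ")
  gk_assert(all(dosages %in% c(0, 1, 2) | is.na(dosages)),
            "dosages must be 0/1/2 or NA")
  if (is.null(variants$id))
    variants$id <- paste0(variants$chrom, ":", variants$pos)
  rownames(dosages) <- variants$id
  structure(list(variants = variants, dosages = dosages),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d variants x %d accessions\n",
              nrow(x$dosages), ncol(x$dosages)))
  invisible(x)
}

#' Accession (or gene) cluster labels
#'
#' @param labels named integer vector, item id -> cluster id in `1..k`.
#' @param k number of clusters.
#' @return An object of class `grouping`.
#' @export
grouping <- function(labels, k = max(labels)) {
  gk_assert(!is.null(names(labels)), "labels must be named by item id")
  gk_assert(all(labels >= 1 & labels <= k), "labels must lie in 1..k")
  structure(list(labels = labels, k = as.integer(k)), class = "grouping")
}

#' @export
print.grouping <- function(x, ...) {
  cat(sprintf("<grouping> %d items in %d clusters (sizes: %s)\n",
              length(x$labels), x$k,
              paste(tabulate(x$labels, x$k), collapse = ", ")))
  invisible(x)
}

## internal: accession ids of one group
group_members <- function(groups, group_id) {
  gk_assert(inherits(groups, "grouping"), "groups must be a grouping")
  ids <- names(groups$labels)[groups$labels == group_id]
  gk_assert(length(ids) > 0, paste("empty group:", group_id))
  ids
}
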