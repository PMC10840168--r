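## File-format boundary.  Internal coordinates are 0-based half-open; GFF3
## and VCF conversions happen here and nowhere else.  Every writer has a
## matching reader so that pipeline stages can be re-run from their
## persisted inputs.

#' Write a genome annotation as GFF3 (+ genome FASTA)
#'
#' Emits `gene` and `CDS` features with `biotype` and `compartment`
#' attributes; if the annotation carries sequences and `fasta` is given,
#' they are written alongside.
#'
#' @param annotation a [genome_annotation()].
#' @param path output GFF3 path.
#' @param fasta optional output FASTA path for the chromosome sequences.
#' @export
write_annotation_gff3 <- function(annotation, path, fasta = NULL) {
  g <- annotation$genes
  gene_gr <- GenomicRanges::GRanges(
    g$chrom, IRanges::IRanges(g$start + 1, g$end), strand = g$strand,
    type = "gene", ID = g$gene_id, biotype = g$biotype,
    compartment = g$compartment
  )
  if (!is.null(g$role)) gene_gr$role <- g$role
  grl <- gene_gr
  if (nrow(annotation$cds) > 0) {
    cd <- annotation$cds
    strand <- g$strand[match(cd$gene_id, g$gene_id)]
    cds_gr <- GenomicRanges::GRanges(
      cd$chrom, IRanges::IRanges(cd$start + 1, cd$end), strand = strand,
      type = "CDS", ID = paste0(cd$gene_id, ".cds"), biotype = NA_character_,
      compartment = NA_character_
    )
    if (!is.null(g$role)) cds_gr$role <- NA_character_
    cds_gr$Parent <- cd$gene_id
    gene_gr$Parent <- NA_character_
    S4Vectors::mcols(cds_gr)$phase <- cd$phase
    S4Vectors::mcols(gene_gr)$phase <- NA_integer_
    grl <- c(gene_gr, cds_gr)
  }
  rtracklayer::export(grl, path, format = "gff3")
  if (!is.null(fasta) && !is.null(annotation$genome)) {
    ss <- Biostrings::DNAStringSet(unlist(annotation$genome))
    Biostrings::writeXStringSet(ss, fasta)
  }
  invisible(path)
}

#' Read a genome annotation from GFF3 (+ optional genome FASTA)
#'
#' @param path GFF3 path with `gene` and `CDS` features as written by
#'   [write_annotation_gff3()].
#' @param fasta optional FASTA path with chromosome sequences.
#' @return A [genome_annotation()].
#' @export
read_annotation_gff3 <- function(path, fasta = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  m <- S4Vectors::mcols(gr)
  is_gene <- m$type == "gene"
  genes <- data.frame(
    gene_id = as.character(m$ID[is_gene]),
    chrom = as.character(GenomicRanges::seqnames(gr)[is_gene]),
    start = GenomicRanges::start(gr)[is_gene] - 1L,
    end = GenomicRanges::end(gr)[is_gene],
    strand = as.character(GenomicRanges::strand(gr)[is_gene]),
    biotype = as.character(m$biotype[is_gene]),
    compartment = as.character(m$compartment[is_gene]),
    stringsAsFactors = FALSE
  )
  if ("role" %in% names(m)) genes$role <- as.character(m$role[is_gene])
  is_cds <- m$type == "CDS"
  cds <- if (any(is_cds)) {
    parent <- m$Parent[is_cds]
    parent <- vapply(as.list(parent), function(x) as.character(x)[1], "")
    data.frame(
      gene_id = parent,
      chrom = as.character(GenomicRanges::seqnames(gr)[is_cds]),
      start = GenomicRanges::start(gr)[is_cds] - 1L,
      end = GenomicRanges::end(gr)[is_cds],
      phase = as.integer(as.character(m$phase[is_cds])),
      stringsAsFactors = FALSE
    )
  } else NULL
  genome <- if (!is.null(fasta)) {
    ss <- Biostrings::readDNAStringSet(fasta)
    setNames(as.character(ss), names(ss))
  } else NULL
  genome_annotation(genes, cds, genome)
}

#' Write binding sites as a BED6+1 file
#'
#' Columns: chrom, start, end, name, score, strand (`.`), fdr.  BED
#' coordinates are 0-based half-open, matching the internal convention.
#'
#' @param sites a [binding_sites()] data.frame.
#' @param path output path.
#' @export
write_sites_bed <- function(sites, path) {
  df <- data.frame(sites$chrom, sites$start, sites$end,
                   paste0("site_", seq_len(nrow(sites))),
                   sites$score, ".", sites$fdr)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read binding sites from a BED6+1 file
#'
#' @param path path written by [write_sites_bed()] (or any BED-like file
#'   with score in column 5 and FDR in column 7).
#' @return A [binding_sites()] data.frame.
#' @export
read_sites_bed <- function(path) {
  df <- read.table(path, sep = "\t", stringsAsFactors = FALSE,
                   col.names = c("chrom", "start", "end", "name", "score",
                                 "strand", "fdr"))
  binding_sites(df$chrom, df$start, df$end, df$score, df$fdr)
}

#' Write a count matrix and its library map as TSV
#'
#' @param counts a [count_matrix()].
#' @param path counts TSV (first column `gene_id`, one column per library).
#' @param map_path library map TSV (`library_id`, `accession_id`).
#' @export
write_counts_tsv <- function(counts, path, map_path) {
  df <- data.frame(gene_id = rownames(counts$values), counts$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  map <- data.frame(library_id = names(counts$library_to_accession),
                    accession_id = unname(counts$library_to_accession))
  write.table(map, map_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count matrix and library map from TSV
#'
#' @param path,map_path files written by [write_counts_tsv()].
#' @return A [count_matrix()].
#' @export
read_counts_tsv <- function(path, map_path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  map <- read.table(map_path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  count_matrix(m, setNames(map$accession_id, map$library_id))
}

#' Write an expression matrix as TSV
#'
#' @param expr an [expression_matrix()].
#' @param path output TSV.
#' @export
write_expression_tsv <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr$values), expr$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix from TSV
#'
#' @param path TSV written by [write_expression_tsv()].
#' @param scale the scale to assert (`"normalized"` or `"relative"`).
#' @return An [expression_matrix()].
#' @export
read_expression_tsv <- function(path, scale = "normalized") {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  if (scale == "relative") m <- m - rowMeans(m)   # absorb rounding
  expression_matrix(m, scale)
}

#' Write a genotype matrix as VCF 4.2
#'
#' Biallelic records with GT fields; dosages 0/1/2 become `0/0`, `0/1`,
#' `1/1`, missing becomes `./.`.  Output is bgzip-compressed (`.vcf.gz`).
#'
#' @param genotypes a [genotype_matrix()].
#' @param path output path (`.vcf.gz`).
#' @export
write_genotypes_vcf <- function(genotypes, path) {
  v <- genotypes$variants
  fix <- cbind(CHROM = v$chrom, POS = as.character(v$pos), ID = v$id,
               REF = v$ref, ALT = v$alt, QUAL = ".", FILTER = "PASS",
               INFO = ".")
  code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gtv <- matrix(code[as.character(genotypes$dosages)],
                nrow = nrow(genotypes$dosages),
                dimnames = dimnames(genotypes$dosages))
  gtv[is.na(gtv)] <- "./."
  gt <- cbind(FORMAT = "GT", gtv)
  meta <- c("##fileformat=VCFv4.2",
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  x <- methods::new(methods::getClassDef("vcfR", package = "vcfR"),
                    meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(x, file = path)
  invisible(path)
}

#' Read a genotype matrix from a VCF
#'
#' Keeps biallelic records only; GT fields are converted to alternate-allele
#' dosages (phased or unphased separators accepted).
#'
#' @param path VCF path (plain or gzipped).
#' @return A [genotype_matrix()].
#' @export
read_genotypes_vcf <- function(path) {
  x <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(x@fix, stringsAsFactors = FALSE)
  biallelic <- !grepl(",", fix$ALT)
  gt <- vcfR::extract.gt(x, element = "GT")
  gt <- gsub("\\|", "/", gt)
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  dos[gt == "0/0"] <- 0L
  dos[gt %in% c("0/1", "1/0")] <- 1L
  dos[gt == "1/1"] <- 2L
  variants <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                         ref = fix$REF, alt = fix$ALT, id = fix$ID,
                         stringsAsFactors = FALSE)
  genotype_matrix(variants[biallelic, , drop = FALSE],
                  dos[biallelic, , drop = FALSE])
}

#' Write / read the long-format climate and photosynthesis CSV tables
#'
#' @param x data.frame as produced by [generate_dataset()].
#' @param path CSV path.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write cluster labels as TSV
#'
#' @param g a [grouping()].
#' @param path output TSV (`item_id`, `cluster`).
#' @export
write_grouping_tsv <- function(g, path) {
  write.table(data.frame(item_id = names(g$labels), cluster = unname(g$labels)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read cluster labels from TSV
#'
#' @param path TSV written by [write_grouping_tsv()].
#' @return A [grouping()].
#' @export
read_grouping_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  grouping(setNames(df$cluster, df$item_id))
}

#' Export a network edge list as TSV and SIF
#'
#' The SIF export (`gene_i pp gene_j`) is loadable in Cytoscape; the TSV
#' carries partial correlations and p-values.
#'
#' @param network a `ggm_network`.
#' @param tsv,sif output paths (either may be `NULL` to skip).
#' @export
write_network <- function(network, tsv = NULL, sif = NULL) {
  if (!is.null(tsv))
    write.table(network$edges, tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(sif)) {
    lines <- sprintf("%s\tpp\t%s", network$edges$gene_i, network$edges$gene_j)
    writeLines(lines, sif)
  }
  invisible(network)
}

#' Write a synthetic bundle to a directory of standard-format files
#'
#' Emits `annotation.gff3`, `genome.fa`, `sites.bed`, `counts.tsv`,
#' `library_map.tsv`, `genotypes.vcf.gz`, `climate.csv`,
#' `photosynthesis.csv`, `network_panel.tsv` and `truth.json`.
#'
#' @param bundle a `synthetic_bundle` from [generate_dataset()].
#' @param dir output directory (created if missing).
#' @return Named character vector of the paths written.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    annotation = file.path(dir, "annotation.gff3"),
    genome = file.path(dir, "genome.fa"),
    sites = file.path(dir, "sites.bed"),
    counts = file.path(dir, "counts.tsv"),
    library_map = file.path(dir, "library_map.tsv"),
    genotypes = file.path(dir, "genotypes.vcf.gz"),
    climate = file.path(dir, "climate.csv"),
    photosynthesis = file.path(dir, "photosynthesis.csv"),
    network_panel = file.path(dir, "network_panel.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_annotation_gff3(bundle$annotation, paths["annotation"], paths["genome"])
  write_sites_bed(bundle$sites, paths["sites"])
  write_counts_tsv(bundle$counts, paths["counts"], paths["library_map"])
  write_genotypes_vcf(bundle$genotypes, paths["genotypes"])
  write_table_csv(bundle$climate, paths["climate"])
  write_table_csv(bundle$photosynthesis, paths["photosynthesis"])
  writeLines(bundle$truth$network_genes, paths["network_panel"])
  truth <- bundle$truth
  ## named vectors serialize as JSON objects only as lists
  truth$accession_groups <- as.list(truth$accession_groups)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(paths)
}

#' Read a synthetic bundle back from a directory
#'
#' @param dir directory written by [write_bundle()].
#' @return List with the same components as a `synthetic_bundle` (the truth
#'   record is re-read from JSON, so data.frames come back as lists of
#'   columns coerced to data.frames).
#' @export
read_bundle <- function(dir) {
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  truth$accession_groups <- unlist(truth$accession_groups)
  structure(list(
    annotation = read_annotation_gff3(file.path(dir, "annotation.gff3"),
                                      file.path(dir, "genome.fa")),
    sites = read_sites_bed(file.path(dir, "sites.bed")),
    counts = read_counts_tsv(file.path(dir, "counts.tsv"),
                             file.path(dir, "library_map.tsv")),
    genotypes = read_genotypes_vcf(file.path(dir, "genotypes.vcf.gz")),
    climate = read_table_csv(file.path(dir, "climate.csv")),
    photosynthesis = read_table_csv(file.path(dir, "photosynthesis.csv")),
    network_panel = readLines(file.path(dir, "network_panel.tsv")),
    truth = truth
  ), class = "synthetic_bundle_files")
}
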