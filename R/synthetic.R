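## Synthetic study generator.
##
## Emulates the shapes of the study inputs (annotation, scored binding
## sites, raw counts with a library map, genotypes, monthly climate,
## photosynthesis parameters) with planted structure: accession groups,
## group-shifted target-gene expression, group-differentiated variants
## (some creating premature stop codons), group-specific network edges and
## a group x condition photosynthesis effect.  Every planted parameter is
## recorded in a truth record for recovery testing.

#' Configuration for the synthetic study generator
#'
#' Defaults define the package's reference study conditions: 200 accessions
#' in two groups of 80 and 120 (alternate- and reference-like), 300 genes of
#' which 50 are focal-TF targets shifted by 3 log2 units in group 2 and 20
#' form the network panel, 500 biallelic SNPs of which 20 are
#' group-differentiated (planted frequencies 0.15 vs 0.75) and 5 of those
#' create premature stop codons, 3 network edges weakened by 0.3 partial
#' correlation points in group 1, a doubled inter-monthly solar-radiation SD
#' in group 2, and a 0.5-point NPQ gain of group 2 under high light.
#'
#' @param n_accessions total number of accessions.
#' @param group_sizes integer vector of planted group sizes (sums to
#'   `n_accessions`); group 2 is the reference-like (high focal-TF) group.
#' @param n_genes total genes in the toy genome (includes a small fraction
#'   of organellar and non-coding decoys).
#' @param n_target_genes number of focal-TF target genes; these carry the
#'   planted expression shift and each receives one binding site.
#' @param n_network_genes size of the network gene panel.
#' @param n_snps,n_causal_snps total and group-differentiated variant counts.
#' @param n_stop_gain how many causal variants are placed inside a CDS such
#'   that the alternate allele creates a stop codon.
#' @param de_log2fc planted expression shift (log2 units) of target genes in
#'   group 2; signs alternate across genes. 0 disables DE planting.
#' @param network_pcor planted partial correlation of network edges, in (0,1).
#' @param n_diff_edges,diff_edge_delta number of differential edges and the
#'   partial-correlation gap (group 2 minus group 1). 0 delta disables.
#' @param nb_dispersion negative-binomial dispersion of the count model.
#' @param libs_per_accession sequencing libraries per accession.
#' @param low_depth_fraction fraction of libraries planted at ~1% of normal
#'   depth (to exercise the library filter); at most one per accession.
#' @param months months per climate year.
#' @param srad_sd_ratio ratio of group-2 to group-1 monthly solar-radiation
#'   SD (>= 1).
#' @param photo_interaction planted NPQ_Lss gain in (group 2, high-light).
#' @param qy_interaction planted QY_max gain in (group 1, high-light).
#' @param seed master seed; each data domain derives its own stream from it.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_accessions = 200,
                             group_sizes = c(80, 120),
                             n_genes = 300,
                             n_target_genes = 50,
                             n_network_genes = 20,
                             n_snps = 500,
                             n_causal_snps = 20,
                             n_stop_gain = 5,
                             de_log2fc = 3,
                             network_pcor = 0.5,
                             n_diff_edges = 3,
                             diff_edge_delta = 0.3,
                             nb_dispersion = 0.05,
                             libs_per_accession = 2,
                             low_depth_fraction = 0.1,
                             months = 12,
                             srad_sd_ratio = 2,
                             photo_interaction = 0.5,
                             qy_interaction = 0.03,
                             seed = 1) {
  cfg <- as.list(environment())
  bad <- function(field) gk_stop(paste("invalid generator config field:", field),
                                 "glknet_config_error")
  if (sum(group_sizes) != n_accessions) bad("group_sizes (must sum to n_accessions)")
  for (f in c("n_accessions", "n_genes", "n_target_genes", "n_network_genes",
              "n_snps", "libs_per_accession", "months"))
    if (cfg[[f]] < 1) bad(f)
  if (any(group_sizes < 1)) bad("group_sizes")
  if (length(group_sizes) < 2) bad("group_sizes (need at least 2 groups)")
  if (n_causal_snps < 0 || n_causal_snps > n_snps) bad("n_causal_snps")
  if (n_stop_gain < 0 || n_stop_gain > n_causal_snps) bad("n_stop_gain")
  if (n_target_genes + n_network_genes > n_genes)
    bad("n_target_genes + n_network_genes (exceeds n_genes)")
  if (network_pcor <= 0 || network_pcor >= 1) bad("network_pcor")
  if (diff_edge_delta < 0 || diff_edge_delta >= network_pcor + 1) bad("diff_edge_delta")
  if (n_diff_edges < 0) bad("n_diff_edges")
  if (n_network_genes < 4 + 2 * n_diff_edges)
    bad("n_network_genes (needs >= 4 + 2*n_diff_edges for the planted graph)")
  if (nb_dispersion <= 0) bad("nb_dispersion")
  if (low_depth_fraction < 0 || low_depth_fraction > 1) bad("low_depth_fraction")
  if (srad_sd_ratio < 1) bad("srad_sd_ratio")
  if (seed != round(seed) || abs(seed) >= 2^24) bad("seed (integer, |seed| < 2^24)")
  structure(cfg, class = "generator_config")
}

#' Precision matrix realizing a requested set of partial correlations
#'
#' Builds the precision matrix with unit diagonal and `-pcor` at each
#' requested off-diagonal position.  Because a standardized precision matrix
#' reproduces its off-diagonal entries as partial correlations
#' (`pcor_ij = -Omega_ij / sqrt(Omega_ii Omega_jj)`), the construction is
#' exact whenever the resulting matrix is positive definite; an edge set for
#' which it is not (e.g. strong cycles) is rejected as infeasible rather
#' than silently deformed.
#'
#' @param genes character vector of panel gene ids.
#' @param edges data.frame with columns `gene_i`, `gene_j`, `pcor`
#'   (|pcor| < 1); an empty data.frame yields the identity.
#' @return Symmetric positive-definite precision matrix with unit diagonal
#'   whose implied partial correlations equal `edges$pcor` exactly.
#' @export
precision_from_edges <- function(genes, edges) {
  p <- length(genes)
  K <- diag(p)
  dimnames(K) <- list(genes, genes)
  if (nrow(edges) > 0) {
    gk_assert(all(abs(edges$pcor) < 1), "edge |pcor| must be < 1")
    i <- match(edges$gene_i, genes)
    j <- match(edges$gene_j, genes)
    gk_assert(!anyNA(i) && !anyNA(j), "edge references gene outside the panel")
    gk_assert(all(i != j), "self-edges are not allowed")
    K[cbind(i, j)] <- -edges$pcor
    K[cbind(j, i)] <- -edges$pcor
  }
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-8)
    gk_stop("infeasible edge set: requested partial correlations admit no positive-definite precision matrix",
            "glknet_infeasible_edges")
  K
}

#' Sample latent expression from a graphical Gaussian model
#'
#' Draws `n` samples from the zero-mean multivariate normal whose precision
#' matrix (after correlation scaling) is `precision`, scaled to marginal
#' standard deviation `sd`.
#'
#' @param precision positive-definite precision matrix (genes x genes).
#' @param n number of samples.
#' @param sd marginal standard deviation of each gene.
#' @return n x genes matrix.
#' @export
sample_network_expression <- function(precision, n, sd = 1) {
  sigma <- stats::cov2cor(solve(precision)) * sd^2
  x <- MASS::mvrnorm(n, mu = rep(0, nrow(precision)), Sigma = sigma)
  if (n == 1) x <- matrix(x, nrow = 1)
  colnames(x) <- rownames(precision)
  x
}

## ---- internal generator pieces -------------------------------------------

GK_GENE_LEN <- 1200L
GK_CDS_OFF <- 150L
GK_CDS_LEN <- 900L
GK_SPACING <- 2000L
GK_LOW_DEPTH_SCALE <- 0.01

random_chrom_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

revcomp <- function(s) {
  chartr("ACGT", "TGCA",
         vapply(s, function(x) paste(rev(strsplit(x, "")[[1]]), collapse = ""), ""))
}

GK_STOPS <- c("TAA", "TAG", "TGA")

## toy genome: 2 nuclear chromosomes plus one organellar, genes non-
## overlapping with fixed spacing; strand drawn at random.
build_annotation <- function(cfg) {
  n <- cfg$n_genes
  n_org <- max(1L, round(0.03 * n))
  n_nc <- max(1L, round(0.03 * n))
  n_panel <- cfg$n_target_genes + cfg$n_network_genes
  gk_assert(n_panel + n_org + n_nc <= n,
            "n_genes too small for panels plus decoy genes")
  gene_id <- sprintf("g%04d", seq_len(n))
  role <- rep("other", n)
  role[seq_len(cfg$n_target_genes)] <- "target"
  role[cfg$n_target_genes + seq_len(cfg$n_network_genes)] <- "network"
  decoy <- n_panel + seq_len(n_org + n_nc)
  compartment <- rep("nuclear", n)
  biotype <- rep("protein_coding", n)
  compartment[decoy[seq_len(n_org)]] <- "organellar"
  biotype[decoy[n_org + seq_len(n_nc)]] <- "ncRNA"
  nuclear <- compartment == "nuclear"
  chrom <- character(n)
  chrom[!nuclear] <- "chrC"
  idx_nuc <- which(nuclear)
  chrom[idx_nuc] <- ifelse(seq_along(idx_nuc) %% 2 == 1, "chr1", "chr2")
  start <- integer(n)
  for (ch in unique(chrom)) {
    k <- which(chrom == ch)
    start[k] <- 1000L + (seq_along(k) - 1L) * (GK_GENE_LEN + GK_SPACING)
  }
  end <- start + GK_GENE_LEN
  strand <- sample(c("+", "-"), n, replace = TRUE)
  genes <- data.frame(gene_id = gene_id, chrom = chrom, start = start,
                      end = end, strand = strand, biotype = biotype,
                      compartment = compartment, role = role,
                      stringsAsFactors = FALSE)
  coding <- biotype == "protein_coding"
  cds <- data.frame(gene_id = gene_id[coding], chrom = chrom[coding],
                    start = start[coding] + GK_CDS_OFF,
                    end = start[coding] + GK_CDS_OFF + GK_CDS_LEN,
                    phase = 0L, stringsAsFactors = FALSE)
  chrom_lens <- vapply(split(end, chrom), function(e) max(e) + 1000L, 0)
  genome <- vapply(chrom_lens, random_chrom_seq, "")
  genome_annotation(genes, cds, genome)
}

## coding sequence of a gene (respecting strand)
coding_sequence <- function(annotation, gene_id) {
  cds <- annotation$cds[annotation$cds$gene_id == gene_id, , drop = FALSE]
  gk_assert(nrow(cds) > 0, paste("gene has no CDS:", gene_id))
  cds <- cds[order(cds$start), , drop = FALSE]
  seqs <- substring(annotation$genome[[cds$chrom[1]]], cds$start + 1, cds$end)
  s <- paste(seqs, collapse = "")
  strand <- annotation$genes$strand[annotation$genes$gene_id == gene_id]
  if (strand == "-") s <- revcomp(s)
  s
}

## find, for one gene, a CDS substitution creating a premature stop codon;
## returns genome-coordinate variant (chrom, pos 1-based, ref, alt) or NULL
find_stop_gain_site <- function(annotation, gene_id) {
  g <- annotation$genes[annotation$genes$gene_id == gene_id, ]
  cds <- annotation$cds[annotation$cds$gene_id == gene_id, ]
  cseq <- coding_sequence(annotation, gene_id)
  n_codon <- nchar(cseq) %/% 3
  for (ci in seq_len(n_codon - 1)) {            # spare the terminal codon
    codon <- substr(cseq, 3 * ci - 2, 3 * ci)
    if (codon %in% GK_STOPS) next
    for (cp in 1:3) {
      for (b in c("A", "C", "G", "T")) {
        if (substr(codon, cp, cp) == b) next
        mutated <- codon
        substr(mutated, cp, cp) <- b
        if (!(mutated %in% GK_STOPS)) next
        coding_off <- 3 * (ci - 1) + (cp - 1)   # 0-based offset in coding seq
        if (g$strand == "+") {
          pos0 <- cds$start + coding_off
          alt <- b
        } else {
          pos0 <- cds$end - 1 - coding_off
          alt <- chartr("ACGT", "TGCA", b)
        }
        ref <- substr(annotation$genome[[g$chrom]], pos0 + 1, pos0 + 1)
        return(data.frame(chrom = g$chrom, pos = pos0 + 1L, ref = ref,
                          alt = alt, gene_id = gene_id,
                          stringsAsFactors = FALSE))
      }
    }
  }
  NULL
}

## planted per-group edge sets: a star around the focal gene plus disjoint
## gene pairs; differential pairs get pcor - delta in group 1.
plant_edges <- function(cfg, net_genes) {
  r <- cfg$network_pcor
  star_size <- max(which(r * sqrt(1:3) < 0.98))
  focal <- net_genes[1]
  star <- data.frame(gene_i = focal, gene_j = net_genes[1 + seq_len(star_size)],
                     pcor = r, stringsAsFactors = FALSE)
  rest <- net_genes[-(1:4)]
  nd <- cfg$n_diff_edges
  diff_pairs <- if (nd > 0) {
    data.frame(gene_i = rest[2 * seq_len(nd) - 1], gene_j = rest[2 * seq_len(nd)],
               pcor = r, stringsAsFactors = FALSE)
  } else star[0, ]
  rest2 <- rest[-seq_len(2 * nd)]
  n_pairs <- length(rest2) %/% 2
  shared <- if (n_pairs > 0) {
    data.frame(gene_i = rest2[2 * seq_len(n_pairs) - 1],
               gene_j = rest2[2 * seq_len(n_pairs)],
               pcor = r, stringsAsFactors = FALSE)
  } else star[0, ]
  ref_edges <- rbind(star, diff_pairs, shared)      # group 2 (reference-like)
  alt_edges <- ref_edges
  if (nd > 0) {
    k <- star_size + seq_len(nd)
    alt_edges$pcor[k] <- r - cfg$diff_edge_delta    # group 1 (alternate-like)
  }
  alt_edges <- alt_edges[abs(alt_edges$pcor) > 1e-12, , drop = FALSE]
  differential <- if (nd > 0 && cfg$diff_edge_delta > 0) {
    data.frame(gene_i = diff_pairs$gene_i, gene_j = diff_pairs$gene_j,
               delta = cfg$diff_edge_delta, stringsAsFactors = FALSE)
  } else data.frame(gene_i = character(), gene_j = character(),
                    delta = numeric())
  list(alt = alt_edges, ref = ref_edges, differential = differential,
       focal = focal)
}

#' Generate a complete synthetic study with planted ground truth
#'
#' @param config a [generator_config()].
#' @return A list of class `synthetic_bundle` with elements `annotation`,
#'   `sites`, `counts` (a [count_matrix()]), `genotypes`
#'   (a [genotype_matrix()]), `climate`, `photosynthesis` (data.frames) and
#'   `truth` (planted parameters: accession groups, DE genes, causal and
#'   stop-gain variants, per-group edges, differential edges, low-depth
#'   libraries and the suggested library filter threshold).
#' @export
generate_dataset <- function(config) {
  gk_assert(inherits(config, "generator_config"),
            "config must come from generator_config()", "glknet_config_error")
  cfg <- config
  n_groups <- length(cfg$group_sizes)
  accessions <- sprintf("acc%03d", seq_len(cfg$n_accessions))
  acc_group <- rep(seq_len(n_groups), cfg$group_sizes)
  names(acc_group) <- accessions

  ## -- structure: annotation, panels, planted edges ------------------------
  st <- with_domain_seed(cfg$seed, "structure", {
    annotation <- build_annotation(cfg)
    genes <- annotation$genes
    target_genes <- genes$gene_id[genes$role == "target"]
    net_genes <- genes$gene_id[genes$role == "network"]
    edges <- plant_edges(cfg, net_genes)
    list(annotation = annotation, target_genes = target_genes,
         net_genes = net_genes, edges = edges)
  })
  annotation <- st$annotation
  genes <- annotation$genes

  ## -- binding sites: one real site inside each target gene + noisy decoys -
  sites <- with_domain_seed(cfg$seed, "sites", {
    tg <- genes[genes$role == "target", ]
    real <- binding_sites(
      chrom = tg$chrom,
      start = tg$start + 300L + sample.int(200L, nrow(tg), replace = TRUE),
      end   = tg$start + 700L + sample.int(200L, nrow(tg), replace = TRUE),
      score = runif(nrow(tg), 8, 15),
      fdr   = 10^-runif(nrow(tg), 12, 20)
    )
    n_decoy <- 20L
    dchrom <- sample(c("chr1", "chr2"), n_decoy, replace = TRUE)
    dstart <- vapply(dchrom, function(ch) {
      lim <- nchar(annotation$genome[[ch]]) - 400L
      sample.int(lim, 1L)
    }, 0L)
    decoy <- binding_sites(dchrom, dstart, dstart + 200L,
                           score = runif(n_decoy, 2, 8),
                           fdr = 10^-runif(n_decoy, 2, 6))
    rbind(real, decoy)
  })

  ## -- counts --------------------------------------------------------------
  n_libs <- cfg$n_accessions * cfg$libs_per_accession
  lib_acc <- rep(accessions, each = cfg$libs_per_accession)
  lib_ids <- paste0(lib_acc, "_L", rep(seq_len(cfg$libs_per_accession),
                                       times = cfg$n_accessions))
  names(lib_acc) <- lib_ids
  de_sign <- rep_len(c(1, -1), cfg$n_target_genes)
  counts_parts <- with_domain_seed(cfg$seed, "counts", {
    base_mu <- rlnorm(cfg$n_genes, meanlog = log(150), sdlog = 1)
    is_net <- genes$role == "network"
    base_mu[is_net] <- rlnorm(sum(is_net), meanlog = log(800), sdlog = 0.3)
    sf <- 2^runif(n_libs, -1, 1)                  # >= 4-fold depth spread
    n_low <- round(cfg$low_depth_fraction * n_libs)
    n_low <- min(n_low, cfg$n_accessions)
    low_libs <- if (n_low > 0) paste0(sample(accessions, n_low), "_L1")
    else character()
    depth <- ifelse(lib_ids %in% low_libs, GK_LOW_DEPTH_SCALE, 1)
    ## group multiplier: planted DE shift of target genes in group 2
    shift <- matrix(0, cfg$n_genes, n_groups)
    if (cfg$de_log2fc != 0)
      shift[genes$role == "target", 2] <- de_sign * cfg$de_log2fc
    mult <- 2^shift
    mu <- base_mu * mult[, acc_group[lib_acc], drop = FALSE]
    mu <- sweep(mu, 2, sf * depth, `*`)
    values <- matrix(
      rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion),
      nrow = cfg$n_genes,
      dimnames = list(genes$gene_id, lib_ids)
    )
    ## network genes: latent MVN on the normalized (log2) scale, converted
    ## deterministically to counts so that planted partial correlations
    ## survive normalization undistorted.
    K_alt <- precision_from_edges(st$net_genes, st$edges$alt)
    K_ref <- precision_from_edges(st$net_genes, st$edges$ref)
    z <- matrix(0, cfg$n_accessions, cfg$n_network_genes,
                dimnames = list(accessions, st$net_genes))
    for (g in seq_len(n_groups)) {
      K <- if (g == 1) K_alt else K_ref
      members <- accessions[acc_group == g]
      z[members, ] <- sample_network_expression(K, length(members), sd = 1)
    }
    net_mu <- base_mu[is_net]
    zt <- t(2^z[lib_acc, , drop = FALSE])         # net genes x libs
    values[is_net, ] <- round(sweep(net_mu * zt, 2, sf * depth, `*`))
    storage.mode(values) <- "integer"
    list(values = values, low_libs = low_libs)
  })
  counts <- count_matrix(counts_parts$values, lib_acc)
  colsums <- colSums(counts_parts$values)
  min_reads <- if (length(counts_parts$low_libs) > 0) {
    low <- colsums[counts_parts$low_libs]
    normal <- colsums[setdiff(lib_ids, counts_parts$low_libs)]
    round(sqrt(max(low) * min(normal)))
  } else 1

  ## -- genotypes -----------------------------------------------------------
  gt <- with_domain_seed(cfg$seed, "genotypes", {
    nuc <- genes[genes$compartment == "nuclear", ]
    n_stop <- cfg$n_stop_gain
    stop_candidates <- nuc$gene_id[nuc$role == "other" &
                                     nuc$biotype == "protein_coding"]
    gk_assert(length(stop_candidates) >= n_stop,
              "not enough spare coding genes for stop-gain planting")
    stop_sites <- do.call(rbind, lapply(
      if (n_stop > 0) sample(stop_candidates, n_stop) else character(),
      function(gid) find_stop_gain_site(annotation, gid)))
    ## intergenic positions for the remaining variants: between genes
    n_rest <- cfg$n_snps - n_stop
    pick_intergenic <- function(n) {
      ch <- sample(c("chr1", "chr2"), n, replace = TRUE)
      pos <- integer(n)
      for (i in seq_len(n)) {
        repeat {
          cand <- sample.int(nchar(annotation$genome[[ch[i]]]), 1L)
          gsub <- genes[genes$chrom == ch[i], ]
          if (!any(cand > gsub$start & cand <= gsub$end)) break
        }
        pos[i] <- cand
      }
      data.frame(chrom = ch, pos = pos, stringsAsFactors = FALSE)
    }
    inter <- pick_intergenic(n_rest)
    inter$ref <- NA_character_
    inter$alt <- NA_character_
    variants <- rbind(
      if (!is.null(stop_sites)) stop_sites[, c("chrom", "pos", "ref", "alt")]
      else inter[0, c("chrom", "pos", "ref", "alt")],
      inter[, c("chrom", "pos", "ref", "alt")]
    )
    ## colliding positions: shift the later (always intergenic) record until
    ## unique, then look up ref bases so they stay faithful to the genome
    key <- paste0(variants$chrom, ":", variants$pos)
    while (anyDuplicated(key)) {
      d <- which(duplicated(key))
      variants$pos[d] <- variants$pos[d] + 1L
      key <- paste0(variants$chrom, ":", variants$pos)
    }
    fill <- which(is.na(variants$ref))
    variants$ref[fill] <- vapply(fill, function(i)
      substr(annotation$genome[[variants$chrom[i]]],
             variants$pos[i], variants$pos[i]), "")
    variants$alt[fill] <- vapply(variants$ref[fill], function(r)
      sample(setdiff(c("A", "C", "G", "T"), r), 1L), "")
    variants$id <- key
    is_causal <- seq_len(cfg$n_snps) %in%
      c(seq_len(n_stop),
        n_stop + sample.int(n_rest, cfg$n_causal_snps - n_stop))
    ## planted alternate-allele frequencies per group
    freq <- matrix(runif(cfg$n_snps, 0.1, 0.9), cfg$n_snps, n_groups)
    if (any(is_causal)) {
      flip <- sample(c(TRUE, FALSE), sum(is_causal), replace = TRUE)
      freq[is_causal, 1] <- ifelse(flip, 0.75, 0.15)
      for (g in seq_len(n_groups)[-1])
        freq[is_causal, g] <- ifelse(flip, 0.15, 0.75)
    }
    dos <- matrix(NA_integer_, cfg$n_snps, cfg$n_accessions,
                  dimnames = list(variants$id, accessions))
    for (g in seq_len(n_groups)) {
      members <- which(acc_group == g)
      dos[, members] <- rbinom(cfg$n_snps * length(members), 2,
                               rep(freq[, g], times = length(members)))
    }
    ord <- order(variants$chrom, variants$pos)
    list(
      genotypes = genotype_matrix(variants[ord, , drop = FALSE],
                                  dos[ord, , drop = FALSE]),
      causal = data.frame(id = variants$id[is_causal],
                          freq_group1 = freq[is_causal, 1],
                          freq_group2 = freq[is_causal, 2],
                          stringsAsFactors = FALSE),
      stop_gain = variants$id[seq_len(n_stop)],
      stop_gain_genes = if (!is.null(stop_sites)) stop_sites$gene_id
      else character()
    )
  })

  ## -- climate: solar radiation with group-scaled seasonal amplitude -------
  climate <- with_domain_seed(cfg$seed, "climate", {
    m <- cfg$months
    season <- sin(2 * pi * (seq_len(m) - 1) / m)
    amp_by_group <- c(3000, 3000 * cfg$srad_sd_ratio,
                      rep(3000, max(0, n_groups - 2)))
    spec <- list(
      srad = list(base = 12000, base_sd = 500, amp = NA, noise = 200),
      tavg = list(base = 10, base_sd = 2, amp = 8, noise = 0.8),
      prec = list(base = 60, base_sd = 10, amp = 20, noise = 5),
      vapr = list(base = 1.2, base_sd = 0.15, amp = 0.3, noise = 0.05),
      wind = list(base = 3.5, base_sd = 0.5, amp = 0.5, noise = 0.2)
    )
    rows <- list()
    for (v in names(spec)) {
      s <- spec[[v]]
      base <- rnorm(cfg$n_accessions, s$base, s$base_sd)
      amp <- if (v == "srad") amp_by_group[acc_group] else rep(s$amp, cfg$n_accessions)
      vals <- outer(base, rep(1, m)) + outer(amp, season) +
        matrix(rnorm(cfg$n_accessions * m, 0, s$noise), cfg$n_accessions)
      df <- data.frame(accession = accessions, variable = v,
                       stringsAsFactors = FALSE)
      colnames(vals) <- sprintf("month_%02d", seq_len(m))
      rows[[v]] <- cbind(df, as.data.frame(vals))
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })

  ## -- photosynthesis: group x condition effects ---------------------------
  photo <- with_domain_seed(cfg$seed, "photo", {
    conds <- c("coastal", "inland")                 # inland = high light
    grid <- expand.grid(accession = accessions, condition = conds,
                        stringsAsFactors = FALSE)
    g <- acc_group[grid$accession]
    inland <- grid$condition == "inland"
    qy_max <- rnorm(nrow(grid), 0.78, 0.02) +
      cfg$qy_interaction * (g == 1 & inland)
    npq <- rnorm(nrow(grid), 1.2, 0.3) +
      cfg$photo_interaction * (g == 2 & inland)
    qy_lss <- rnorm(nrow(grid), 0.55, 0.05)
    out <- rbind(
      data.frame(grid, parameter = "QY_max", value = pmin(pmax(qy_max, 0), 1)),
      data.frame(grid, parameter = "NPQ_Lss", value = pmax(npq, 0)),
      data.frame(grid, parameter = "QY_Lss", value = pmin(pmax(qy_lss, 0), 1))
    )
    rownames(out) <- NULL
    out
  })

  de_genes <- if (cfg$de_log2fc != 0) {
    data.frame(gene_id = st$target_genes,
               log2fc_group2_vs_group1 = de_sign * cfg$de_log2fc,
               stringsAsFactors = FALSE)
  } else data.frame(gene_id = character(), log2fc_group2_vs_group1 = numeric())

  truth <- list(
    accession_groups = acc_group,
    group_sizes = cfg$group_sizes,
    target_genes = st$target_genes,
    network_genes = st$net_genes,
    focal_gene = st$edges$focal,
    de_genes = de_genes,
    causal_snps = gt$causal,
    stop_gain_variants = gt$stop_gain,
    stop_gain_genes = gt$stop_gain_genes,
    planted_edges_per_group = list(group1 = st$edges$alt,
                                   group2 = st$edges$ref),
    differential_edges = st$edges$differential,
    low_depth_libraries = counts_parts$low_libs,
    min_reads = min_reads,
    seed = cfg$seed
  )

  structure(list(annotation = annotation, sites = sites, counts = counts,
                 genotypes = gt$genotypes, climate = climate,
                 photosynthesis = photo, truth = truth, config = cfg),
            class = "synthetic_bundle")
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat(sprintf(
    "<synthetic_bundle> %d accessions (%s), %d genes, %d sites, %d variants\n",
    x$config$n_accessions, paste(x$config$group_sizes, collapse = "+"),
    x$config$n_genes, nrow(x$sites), nrow(x$genotypes$variants)))
  invisible(x)
}
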