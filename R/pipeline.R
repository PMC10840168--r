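## End-to-end orchestration: every stage reads and writes standard formats
## so that any synthetic input can be replaced by real data of the same
## shape.  The stage order mirrors the analysis it reproduces:
##   targets -> expression -> clustering -> differential expression ->
##   climate contrasts -> GWAS -> per-group networks -> edge comparison ->
##   photosynthesis contrasts.

#' Pipeline configuration
#'
#' Houses every numeric threshold of the analysis with the study values as
#' defaults: top 100 sites at site FDR < 7.2e-11, a 1 kb symmetric target
#' window, a 1e6-read library filter, three clusters on each axis,
#' DE bounds FDR < 0.01 and |log2FC| > 2, GWAS bounds p < 1e-10 and
#' frequency > 25%, network edge alpha 0.05, focal neighborhood alpha 0.01
#' expanded 5 steps, and a 0.2-point differential-edge rule.
#'
#' @param input_dir directory holding the input files (the layout written
#'   by [write_bundle()]).
#' @param output_dir directory for stage artifacts and the run report.
#' @param top_n_sites,site_fdr,window_up,window_down target definition.
#' @param min_library_reads library filter threshold (`NULL`: use the
#'   bundle's suggested value from `truth.json` when present, else 1e6).
#' @param k_gene_clusters,k_accession_clusters biclustering cut sizes.
#' @param de_fdr,de_lfc differential-expression bounds.
#' @param gwas_p,gwas_freq GWAS bounds.
#' @param edge_alpha,neighborhood_alpha,neighborhood_steps,edge_delta
#'   network inference and comparison parameters.
#' @param months months per climate year.
#' @param focal_gene focal gene id (`NULL`: taken from `truth.json` when
#'   present).
#' @param reference_group,alternate_group accession cluster ids used for all
#'   two-group contrasts; defaults 1 and 2, i.e. the two largest expression
#'   clusters (cluster ids are assigned by decreasing size).
#' @param seed seed echoed into the report (all pipeline stages are
#'   deterministic; only data generation consumes randomness).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir, output_dir,
                            top_n_sites = 100, site_fdr = 7.2e-11,
                            window_up = 1000, window_down = 1000,
                            min_library_reads = NULL,
                            k_gene_clusters = 3, k_accession_clusters = 3,
                            de_fdr = 0.01, de_lfc = 2.0,
                            gwas_p = 1e-10, gwas_freq = 0.25,
                            edge_alpha = 0.05, neighborhood_alpha = 0.01,
                            neighborhood_steps = 5, edge_delta = 0.2,
                            months = 12, focal_gene = NULL,
                            reference_group = 1, alternate_group = 2,
                            seed = 1) {
  cfg <- as.list(environment())
  gk_assert(de_fdr > 0 && de_fdr < 1 && gwas_p > 0 && gwas_p < 1 &&
              edge_alpha >= 0 && edge_alpha <= 1 &&
              neighborhood_alpha > 0 && neighborhood_alpha <= 1,
            "a threshold lies outside its domain", "glknet_config_error")
  gk_assert(k_accession_clusters >= 2 && k_gene_clusters >= 2,
            "cluster counts must be >= 2", "glknet_config_error")
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes all stages from the files in `config$input_dir`, writes each
#' stage's TSV/SIF artifacts plus a machine-readable `report.json` into
#' `config$output_dir`, and returns the report.  Fully deterministic given
#' the inputs and configuration; re-running reproduces every artifact
#' byte-for-byte (wall times live only in the report).
#'
#' @param config a [pipeline_config()].
#' @return The run report (list), invisibly also written as JSON.
#' @export
run_pipeline <- function(config) {
  gk_assert(inherits(config, "pipeline_config"), "config must be a pipeline_config")
  ind <- config$input_dir
  outd <- config$output_dir
  dir.create(outd, showWarnings = FALSE, recursive = TRUE)
  report <- list(config = config[setdiff(names(config), c())], stages = list())
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(
      tryCatch(expr, error = function(e) {
        file.create(file.path(outd, paste0(name, ".partial")))
        gk_stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                "glknet_stage_error")
      }),
      message = function(m) invokeRestart("muffleMessage")
    )
    list(result = res, wall_time = proc.time()[["elapsed"]] - t0)
  }

  ## -- inputs --------------------------------------------------------------
  annotation <- read_annotation_gff3(file.path(ind, "annotation.gff3"),
                                     file.path(ind, "genome.fa"))
  sites <- read_sites_bed(file.path(ind, "sites.bed"))
  counts <- read_counts_tsv(file.path(ind, "counts.tsv"),
                            file.path(ind, "library_map.tsv"))
  truth_path <- file.path(ind, "truth.json")
  truth <- if (file.exists(truth_path))
    jsonlite::read_json(truth_path, simplifyVector = TRUE) else NULL
  min_reads <- config$min_library_reads
  if (is.null(min_reads))
    min_reads <- if (!is.null(truth$min_reads)) truth$min_reads else 1e6
  focal <- config$focal_gene
  if (is.null(focal)) {
    gk_assert(!is.null(truth$focal_gene),
              "focal_gene not configured and no truth.json to take it from")
    focal <- truth$focal_gene
  }

  ## -- stage: targets ------------------------------------------------------
  st <- t_stage("targets", {
    top <- select_top_sites(sites, n = config$top_n_sites,
                            max_fdr = config$site_fdr)
    tg <- assign_sites_to_genes(top, annotation,
                                upstream = config$window_up,
                                downstream = config$window_down)
    writeLines(tg, file.path(outd, "target_genes.tsv"))
    list(n_sites_in = nrow(sites), n_sites_selected = nrow(top),
         n_targets = length(tg), targets = tg)
  })
  targets <- st$result$targets
  report$stages$targets <- st[c("result", "wall_time")]
  report$stages$targets$result$targets <- NULL

  ## -- stage: expression ---------------------------------------------------
  st <- t_stage("expression", {
    c1 <- filter_genes(counts, annotation)
    c2 <- filter_libraries(c1, min_reads)
    c3 <- merge_by_accession(c2)
    norm <- normalize_counts(c3)
    rel <- relative_expression(norm)
    write_expression_tsv(norm, file.path(outd, "expression_normalized.tsv"))
    write_expression_tsv(rel, file.path(outd, "expression_relative.tsv"))
    list(n_genes_in = nrow(counts$values), n_genes_kept = nrow(c1$values),
         n_libraries_in = ncol(c1$values), n_libraries_kept = ncol(c2$values),
         libraries_removed = attr(c2, "removed"),
         n_accessions = ncol(c3$values), min_library_reads = min_reads,
         norm = norm, rel = rel)
  })
  norm <- st$result$norm
  rel <- st$result$rel
  report$stages$expression <- st[c("result", "wall_time")]
  report$stages$expression$result$norm <- NULL
  report$stages$expression$result$rel <- NULL

  ## -- stage: clustering (on the candidate-target panel) -------------------
  st <- t_stage("clustering", {
    panel <- intersect(targets, rownames(rel$values))
    sub <- expression_matrix(
      rel$values[panel, , drop = FALSE] -
        rowMeans(rel$values[panel, , drop = FALSE]), "relative")
    bic <- hierarchical_bicluster(sub, k_genes = config$k_gene_clusters,
                                  k_accessions = config$k_accession_clusters)
    write_grouping_tsv(bic$genes, file.path(outd, "gene_clusters.tsv"))
    write_grouping_tsv(bic$accessions, file.path(outd, "accession_clusters.tsv"))
    list(n_panel_genes = length(panel),
         gene_cluster_sizes = tabulate(bic$genes$labels, bic$genes$k),
         accession_cluster_sizes = tabulate(bic$accessions$labels,
                                            bic$accessions$k),
         groups = bic$accessions)
  })
  groups <- st$result$groups
  report$stages$clustering <- st[c("result", "wall_time")]
  report$stages$clustering$result$groups <- NULL

  ref_g <- config$reference_group
  alt_g <- config$alternate_group
  gk_assert(all(c(ref_g, alt_g) %in% groups$labels),
            "reference/alternate group absent from the clustering",
            "glknet_config_error")

  ## -- stage: differential expression (alternate vs reference) -------------
  st <- t_stage("diffexpr", {
    de <- differential_expression(norm, groups, group_a = alt_g,
                                  group_b = ref_g,
                                  fdr_threshold = config$de_fdr,
                                  lfc_threshold = config$de_lfc)
    write.table(de, file.path(outd, "differential_expression.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    list(n_genes_tested = nrow(de), n_significant = sum(de$significant),
         n_up_in_alternate = sum(de$significant & de$log2fc > 0),
         n_up_in_reference = sum(de$significant & de$log2fc < 0),
         de = de)
  })
  de_table <- st$result$de
  report$stages$diffexpr <- st[c("result", "wall_time")]
  report$stages$diffexpr$result$de <- NULL

  ## -- stage: climate contrasts --------------------------------------------
  st <- t_stage("climate", {
    climate <- read_table_csv(file.path(ind, "climate.csv"))
    summ <- monthly_summary(climate, months = config$months)
    tests <- climate_group_tests(summ, groups, group_a = alt_g,
                                 group_b = ref_g)
    write.table(tests, file.path(outd, "climate_tests.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    list(n_variables = length(unique(summ$variable)),
         top_variable = paste(tests$variable[1], tests$statistic[1]),
         top_p = tests$p_value[1], tests = tests)
  })
  climate_tests <- st$result$tests
  report$stages$climate <- st[c("result", "wall_time")]
  report$stages$climate$result$tests <- NULL

  ## -- stage: GWAS ---------------------------------------------------------
  st <- t_stage("gwas", {
    genotypes <- read_genotypes_vcf(file.path(ind, "genotypes.vcf.gz"))
    assoc <- allelic_chisq(genotypes, groups, group_a = alt_g, group_b = ref_g)
    assoc <- annotate_consequences(assoc, annotation)
    candidates <- filter_variants(assoc, p_threshold = config$gwas_p,
                                  freq_min = config$gwas_freq,
                                  impact_in = "HIGH")
    write.table(assoc, file.path(outd, "association.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(candidates, file.path(outd, "candidate_variants.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    cascade <- attr(candidates, "cascade")
    list(cascade = as.list(cascade), n_candidates = nrow(candidates),
         candidates = candidates)
  })
  candidates <- st$result$candidates
  report$stages$gwas <- st[c("result", "wall_time")]
  report$stages$gwas$result$candidates <- NULL

  ## -- stage: per-group networks -------------------------------------------
  st <- t_stage("ggm", {
    panel <- readLines(file.path(ind, "network_panel.tsv"))
    nets <- list()
    for (g in c(ref_g, alt_g)) {
      members <- intersect(names(groups$labels)[groups$labels == g],
                           colnames(norm$values))
      sub <- expression_matrix(norm$values[, members, drop = FALSE],
                               "normalized")
      net <- build_network(sub, panel = panel, alpha = config$edge_alpha)
      tag <- if (g == ref_g) "reference" else "alternate"
      write_network(net,
                    tsv = file.path(outd, paste0("network_", tag, ".tsv")),
                    sif = file.path(outd, paste0("network_", tag, ".sif")))
      nets[[tag]] <- net
    }
    list(n_panel = length(panel),
         n_edges_reference = nrow(nets$reference$edges),
         n_edges_alternate = nrow(nets$alternate$edges),
         lambda_reference = nets$reference$lambda,
         lambda_alternate = nets$alternate$lambda,
         nets = nets)
  })
  nets <- st$result$nets
  report$stages$ggm <- st[c("result", "wall_time")]
  report$stages$ggm$result$nets <- NULL

  ## -- stage: neighborhood + differential edges ----------------------------
  st <- t_stage("netcompare", {
    hood <- extract_neighborhood(nets$reference, focal = focal,
                                 alpha = config$neighborhood_alpha,
                                 steps = config$neighborhood_steps)
    cmp <- compare_edge_strengths(nets$reference, nets$alternate,
                                  alpha = config$neighborhood_alpha,
                                  delta_threshold = config$edge_delta)
    writeLines(hood, file.path(outd, "neighborhood_genes.tsv"))
    write.table(cmp, file.path(outd, "differential_edges.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    list(focal_gene = focal, n_neighborhood = length(hood),
         n_compared = nrow(cmp), n_flagged = sum(cmp$flagged), cmp = cmp)
  })
  report$stages$netcompare <- st[c("result", "wall_time")]
  diff_edges <- st$result$cmp
  report$stages$netcompare$result$cmp <- NULL

  ## -- stage: photosynthesis contrasts -------------------------------------
  st <- t_stage("photo", {
    photo <- read_table_csv(file.path(ind, "photosynthesis.csv"))
    tests <- photosynthesis_tests(photo, groups, group_a = alt_g,
                                  group_b = ref_g)
    write.table(tests, file.path(outd, "photosynthesis_tests.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    list(n_tests = nrow(tests))
  })
  report$stages$photo <- st[c("result", "wall_time")]

  report$seed <- config$seed
  rep_out <- report
  jsonlite::write_json(rep_out, file.path(outd, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(structure(list(report = report, groups = groups,
                           de = de_table, climate_tests = climate_tests,
                           candidates = candidates, networks = nets,
                           differential_edges = diff_edges),
                      class = "pipeline_result"))
}
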