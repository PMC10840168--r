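# glknet

Accession-stratified analysis of GLK1-centered regulatory variation in
*Arabidopsis thaliana*.

## The problem

GOLDEN2-LIKE 1 (GLK1) is a transcription factor that drives chloroplast
biogenesis and the expression of photosynthesis-associated nuclear genes.
Natural Arabidopsis accessions differ in the basal activity of the
GLK1-centered regulatory network, and that variation tracks the climate of
their collection sites and their capacity to acclimate to high light.
`glknet` packages the full analysis chain needed to study such variation —
for computational biologists who want each stage as a tested, reusable
component rather than a one-off script:

* candidate target definition from scored binding sites (top-*n* after a
  site-FDR bound; gene window 1 kb upstream to 1 kb downstream);
* RNA-seq count processing per accession (gene and library filters,
  merging, median-of-ratios normalization, relative expression);
* joint hierarchical biclustering of genes and accessions into groups;
* Welch differential expression with Benjamini–Hochberg control
  (FDR < 0.01, |log2FC| > 2, both strict);
* per-accession monthly climate summaries and ranked group contrasts;
* allelic chi-square GWAS between accession groups (PLINK `--assoc`
  convention) with a codon-level consequence caller and the candidate
  cascade p < 1e-10 → frequency > 25% → exonic → HIGH impact;
* per-group graphical Gaussian networks via Schäfer–Strimmer shrinkage
  partial correlations, `pcor_ij = -Ω_ij/√(Ω_ii Ω_jj)` with
  `Ω = (λI + (1-λ)R)^-1`, and edge p-values from the analytic null
  `f0(r;κ) ∝ (1-r²)^((κ-3)/2)` with κ fitted by maximum likelihood;
* focal-gene neighborhood extraction (breadth-first, 5 steps at p < 0.01)
  and differential-edge comparison between groups (flag rule: |Δpcor| >
  0.2);
* group × light-condition contrasts of photosynthesis parameters
  (QY_max, NPQ_Lss, QY_Lss);
* a synthetic-data generator that emits every input format with planted
  ground truth (groups, DE genes, causal and stop-gain variants,
  group-specific network edges, climate and photosynthesis effects) for
  end-to-end recovery testing.

All stages read and write standard formats (GFF3 + FASTA, BED-like sites,
TSV count/expression matrices, VCF 4.2, CSV tables, SIF edge lists), so
real data of the same shape can replace any synthetic input. The methods
vignette (`vignettes/glknet-methods.Rmd`) documents the models,
assumptions and every resolved design choice.

## Worked example

Generate a synthetic study at the default conditions (200 accessions in
groups of 80 + 120, 300 genes, 500 SNPs) and run the whole pipeline:

```r
library(glknet)

b <- generate_dataset(generator_config(seed = 1))
#> <synthetic_bundle> 200 accessions (80+120), 300 genes, 70 sites, 500 variants

dir <- tempfile()
write_bundle(b, file.path(dir, "in"))
cfg <- pipeline_config(file.path(dir, "in"), file.path(dir, "out"),
                       k_gene_clusters = 2, k_accession_clusters = 2)
res <- run_pipeline(cfg)
```

What the run report shows, and what it means:

```
targets:    50 candidate target genes
clusters:   120 + 80 accessions; ARI vs planted groups = 1
DE:         50 significant genes ( 25 up in alternate, 25 up in reference )
climate:    top variable = srad sd   p = 8.71e-234
GWAS cascade: 500 -> 20 -> 5 -> 5 -> 5
<ggm_network> 20 genes, 12 edges at alpha=0.05 (lambda=0.307, kappa=104.6)
neighborhood of g0051 : 4 genes; 2 differential edges flagged
```

* All 50 planted binding sites map back to exactly the 50 planted target
  genes; the site-FDR bound removes the 20 decoy sites first.
* Biclustering the target panel recovers the planted accession groups
  perfectly (adjusted Rand index 1); cluster 1 is the largest group by
  convention and serves as the reference downstream.
* Differential expression finds exactly the 50 planted genes (25 shifted
  up, 25 down) and nothing else at FDR < 0.01, |log2FC| > 2.
* Among the climate variables, the monthly standard deviation of solar
  radiation — the one planted group difference — ranks first.
* The GWAS cascade reads: 500 variants tested → 20 below p = 1e-10 (the
  20 planted causal variants) → 5 also common, exonic and HIGH-impact →
  all 5 are the planted stop-codon variants.
* The reference-group network recovers the planted edges; the three
  planted differential edges carry the largest between-group differences:

```r
head(res$differential_edges, 3)
#>   gene_i gene_j strength_ref strength_alt     delta flagged
#> 1  g0057  g0058    0.3910142   0.03485101 0.3561632    TRUE
#> 2  g0055  g0056    0.3583714   0.14134908 0.2170223    TRUE
#> 3  g0059  g0060    0.3303502   0.16005813 0.1702920   FALSE
```

Shrinkage attenuates partial correlations at this group size (λ ≈ 0.3), so
the planted 0.3-point differences shrink toward the 0.2 flag rule; at 1000
accessions per group all planted differential edges are flagged (the test
suite verifies this). The ranking by |delta| puts the planted edges on top
either way.

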