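Package: glknet
Title: Accession-Stratified Analysis of GLK1-Centered Regulatory Variation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to stratify natural Arabidopsis accessions by the expression
    of candidate GLK1 target genes and to contrast the resulting groups at
    every level of a regulatory analysis: candidate-target definition from
    scored transcription-factor binding sites, library filtering and
    median-of-ratios normalization of raw RNA-seq counts, joint hierarchical
    biclustering of genes and accessions, Welch differential expression with
    Benjamini-Hochberg control, allelic chi-square association between groups
    with a codon-level variant-consequence caller, per-group graphical
    Gaussian network inference via Schaefer-Strimmer shrinkage partial
    correlations with an analytic null for edge significance, differential
    edge comparison around a focal gene, and group-by-condition contrasts of
    climate and photosynthesis parameters. A synthetic-data generator with
    planted ground truth (accession groups, differentially expressed genes,
    causal variants, group-specific network edges) supports end-to-end
    recovery testing of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    MASS,
    jsonlite,
    vcfR,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
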