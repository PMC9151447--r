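Package: AncestryOmics
Title: Ancestry-Stratified Multi-Omics Regulatory Analysis for Tumor Cohorts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for comparing tumor cohorts of African and
    European genetic ancestry across omics layers: principal-component
    nearest-centroid ancestry assignment against a labeled reference panel,
    demographic contingency testing with Benjamini-Hochberg adjustment,
    multi-caller somatic mutation consolidation with tumor mutation burden and
    a hotspot concentration score, covariate-adjusted differential expression,
    marker-based immune cell deconvolution with rank-sum and two-way ANOVA
    comparisons, promoter motif scanning with composite cis-regulatory module
    discovery by genetic algorithm, master-regulator search over a directed
    signaling network with positive-feedback detection, 450K-style
    differential methylation with methylation-expression integration, and a
    synthetic-data generator that plants known effects in every layer so each
    stage carries a parameter-recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    Biostrings,
    car,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: GeneExpression, DNAMethylation, Transcription, NetworkInference,
    DifferentialExpression, DifferentialMethylation, ImmunoOncology
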