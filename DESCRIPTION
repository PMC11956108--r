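Package: mmgp
Title: Metabolic Marker-Assisted Genomic Prediction for Hybrid Breeding
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for predicting hybrid crop performance from parental
    genome-wide markers and parental metabolomes. Implements metabolome-wide
    association scans based on LASSO first-entry p-values to select
    trait-associated metabolic markers, additive and dominance metabolite
    coding of hybrids from their parents, multi-kernel GBLUP with REML
    variance-component estimation and block-partitioned prediction of
    untested crosses, a gradient-boosted-tree alternative with
    tree-structured Parzen estimator hyperparameter tuning, repeated
    k-fold cross-validation of five model configurations (GP, MP, MMP,
    M_GP, MM_GP), exhaustive diallel cross ranking with selection-gain
    summaries, and a synthetic-data generator emulating a sparse partial
    diallel with replicated metabolite intensities.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    methods,
    glmnet,
    jsonlite,
    data.table,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    VariantAnnotation,
    S4Vectors,
    SummarizedExperiment,
    GenomicRanges
Config/testthat/edition: 3
RoxygenNote: 7.3.3
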