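Package: regdyn
Title: Dynamic Regulatory Module Networks from Paired Expression and
    Chromatin Accessibility Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Integrative analysis of RNA-seq and ATAC-seq time courses for
    regulatory genomics. Aggregates per-bp chromatin accessibility into
    promoter and motif-level signal matrices, merges per-time-point peak
    calls into universal peaks, clusters expression into per-time-point
    level modules with a non-stationary Gaussian mixture, extracts and
    clusters transitioning genes, tests expression-accessibility
    correlation against permutation nulls, learns fused-lasso dynamic
    regulatory module networks (DRMN) with cross-validated hyperparameter
    selection and boundary t-test regulator prioritization, and infers
    fine-grained regulator-target edges with a multi-task group LASSO
    (MTG-LASSO) under leave-one-out selection frequency and randomized
    nulls. Ships a synthetic-data generator that plants the statistical
    structure every stage assumes, so the full pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    cluster,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    limma,
    mclust,
    purrr,
    Rcpp,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    knitr,
    rmarkdown,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
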