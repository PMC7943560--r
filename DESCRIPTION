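Package: stepnet
Title: Stepwise Integrative Correlation-Network Analysis of
    Microbiota-Host-Symptom Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Implements a stepwise integrative analysis pipeline for
    multi-layer cohort data combining mucosal host gene expression,
    mucosa-adjacent microbiota counts and symptom scores: median-of-ratios
    count normalization, taxonomic summarization of genera into phyla,
    PCA-based multivariate outlier screening per group, all-pairs Spearman
    correlation networks with strength- and significance-based density
    statistics, modularity-based detection of intercorrelation clusters,
    comparison of network patterns between patients and controls, multilayer
    models joining mucosal and symptom layers by significant between-layer
    correlations, and de-summarization of selected phyla for genus-level
    re-analysis. Includes a Gaussian-copula cohort simulator with planted
    cross-layer rank-correlation structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
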