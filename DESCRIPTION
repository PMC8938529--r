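Package: stressconcord
Title: Cross-Model Transcriptomic Concordance for Stress Susceptibility and Resilience
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Links bulk RNA-seq experiments from two preclinical stress models
    (chronic oral corticosterone by BDNF Val66Met genotype, and chronic social
    defeat stress by housing condition) through a reproducible concordance
    pipeline: moderated-t differential expression on log-CPM, stratified
    rank-rank hypergeometric overlap (RRHO) with per-quadrant peak gene sets,
    consensus weighted co-expression modules (soft-threshold adjacency,
    topological overlap, calibrated consensus, tree-based branch cutting,
    eigengenes and kME), module-by-DEG-set Fisher enrichment with BH-FDR,
    a differential-expression relevance score, cross-model key-module flags,
    mu-plus-sigma hub-gene selection, and behavioral emotionality composites
    with control-referenced z-scoring. Ships a synthetic-data generator with
    planted co-expression modules and concordant differential expression so
    every stage is testable end to end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    fgsea,
    limma,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
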