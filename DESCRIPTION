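Package: spermdyn
Title: Developmental Staging and Sex Chromosome Dynamics in Spermatogenesis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A modular, fully testable reimplementation of a droplet
    single-cell, bulk time-course and low-input chromatin profiling
    analysis of mouse spermatogenesis. Covers ambient-RNA based empty
    droplet recovery, pooled size-factor normalisation, highly variable
    gene selection, shared nearest-neighbour clustering, principal-curve
    pseudotime ordering, marker gene detection with batch blocking,
    probabilistic staging of bulk RNA-seq samples onto single-cell
    clusters, X-to-autosome expression ratios for meiotic sex chromosome
    inactivation, an empirical-null transcriptional complexity
    correlation screen, fold-change-threshold negative binomial testing
    for de novo X-linked escape gene calling, differential cell-type
    proportion testing, and CUT&RUN-style fragment counting, high-signal
    region merging and repeat enrichment. A synthetic data generator
    plants known truth (stage programs, silencing factors, escape genes,
    promoter enrichment) so every stage of the pipeline is verifiable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    igraph,
    limma,
    GenomicRanges,
    IRanges,
    S4Vectors,
    generics,
    data.table,
    withr
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    scran
Config/testthat/edition: 3
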