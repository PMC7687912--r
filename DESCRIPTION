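Package: ernarch
Title: Enhancer Transcription QTLs and Bipartite Enhancer Architecture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pipeline for population-scale analysis of bidirectional
    enhancer transcription measured by strand-specific 5'-end nascent-RNA
    count tracks (PRO-cap-like data). Calls nascent transcription start
    sites and pairs them into divergent transcribed regulatory elements
    (tTREs), classifies promoters versus enhancers, normalizes initiation
    phenotypes (level and directionality index), maps cis quantitative
    trait loci for initiation level (tiQTLs), directionality (diQTLs) and
    gene expression (eQTLs) with principal-component covariates, filters
    to likely-primary variants, and characterizes the bipartite enhancer
    architecture: positional QTL enrichment with resampled background
    bands, a center/core/NCNC/out/far-out region partition, and
    allele-level motif scoring (PWM deltas, Initiator likelihood, and
    TATA-like elements). Includes a synthetic-data generator with planted
    effects so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    stats,
    utils,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    limma,
    pROC,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
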