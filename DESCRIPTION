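Package: npxflow
Title: Simulation and Analysis of Proximity Extension Assay Plasma Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for next-generation proximity
    extension assay (PEA) plasma proteome profiling. Simulates assay-level
    sequencing counts with the five classes of internal controls on
    randomized plates, converts counts to Normalized Protein eXpression
    (NPX) with sample quality-control flags and limits of detection,
    performs plate, batch (bridging) and cross-platform normalization,
    decomposes longitudinal protein variation into inter- and
    intra-individual coefficients of variation, maps protein quantitative
    trait loci (pQTL) with cis/trans classification, LD pruning and
    conditional analysis, and associates protein levels with clinical
    parameters including differential expression, mixed-effect models and
    patient stratification by BMI and drug response. All stages operate on
    long-format tibbles and compose with the pipe; a synthetic-data
    generator with recorded ground truth supports end-to-end recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    stringr,
    stats,
    utils,
    generics,
    ggplot2,
    lme4,
    lmerTest,
    jsonlite,
    yaml,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    cluster
Config/testthat/edition: 3
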