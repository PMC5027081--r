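Package: oacgh
Title: Copy-Number Aberration Calling and Subtype Classification for
    Two-Color Array CGH
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-style workflow for oligonucleotide array
    comparative genomic hybridization (oaCGH) profiles of canine
    leukemia/lymphoma samples: robust normalization of two-color signal
    ratios (kernel-density mode centering, mean-absolute-deviation
    scaling), circular binary segmentation with a permutation null,
    gain/loss calling by fixed log2 thresholds and by robust
    dichotomization, genome-imbalance summaries, Ward/Euclidean
    co-clustering classification against subtype-labeled reference
    cohorts, FISH copy-number concordance scoring, and companion
    expression computations (variance filtering, signed fold changes,
    comparative-Ct quantification). Includes synthetic-data generators
    with planted ground truth for every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    Rcpp,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
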