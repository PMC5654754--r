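Package: adabf
Title: Adaptive Combination of Bayes Factors for Rare and Common Variant
    Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gene- and region-based association testing that jointly analyses
    rare and common variants by adaptively combining Wakefield approximate
    Bayes factors across the variants of a region. Supports case-parent trios
    (transmission disequilibrium counts) and unrelated subjects (per-variant
    linear or logistic regression), assesses region-level significance by
    correlated multivariate-normal null resampling with a sequential
    escalation schedule, and ships the adaptive combination of P-values (ADA)
    competitor, an unweighted burden baseline, and a synthetic-genotype
    simulator with an L-shaped allele-frequency spectrum for calibration and
    power experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
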