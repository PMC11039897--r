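Package: mrscreen
Title: Bidirectional Two-Sample Mendelian Randomization Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A tidyverse-native toolkit for screening many exposures against
    an outcome with two-sample Mendelian randomization from GWAS summary
    statistics. Covers instrument selection (p-value thresholding, greedy LD
    clumping, per-variant R2 and F statistics), harmonisation of effect
    alleles with frequency-based rescue of palindromic variants, the
    inverse-variance-weighted, MR-Egger, weighted-median and Wald-ratio
    estimators with a Cochran's Q driven fixed/random-effects rule,
    MR-PRESSO global and outlier resampling tests, Benjamini-Hochberg FDR
    with two-tier significance calling, Bayesian colocalization via
    per-variant approximate Bayes factors, and MCODE dense-subnetwork
    discovery on protein-interaction graphs. A synthetic summary-statistics
    generator with known ground truth makes every stage testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    generics,
    withr,
    igraph,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
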