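Package: seasonscan
Title: Genome Scans for Parallel Seasonal Adaptation from Pooled Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects parallel seasonal adaptation from paired spring/fall
    pooled-sequencing allele frequencies. Implements effective-coverage
    correction for pool-seq read counts, a weighted binomial seasonal
    regression with within-pair label permutations, a rank-normalized
    Fisher's-method statistic combining per-pair exact tests, enrichment of
    seasonal sites relative to chromosomal inversions, matched-control
    resampling, seasonal-clinal concordance along latitude, a leave-one-out
    predictability analysis, and environmental models including a
    thermal-limit grid scan over daily temperature series. Ships a
    synthetic-data generator with known ground truth so every stage of the
    pipeline can be calibrated and power-tested.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    geosphere,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
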