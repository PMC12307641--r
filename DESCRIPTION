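Package: loyscan
Title: Mosaic Loss of Chromosome Y Calling and Treatment Association Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls mosaic loss of chromosome Y (mLOY) from SNP-array log R
    ratio data via the median signal over male-specific-region probes
    (mLRR-Y), under both an absolute threshold and per-cohort percentile
    thresholds, and associates mLOY with radiotherapy and other clinical
    covariates: Fisher exact r x c tests, adjusted logistic regression,
    time-since-treatment stratification, per-Gy dose-response models, and
    two-level inverse-variance fixed-effect meta-analysis with Cochran's Q
    and I-squared heterogeneity statistics. Includes a synthetic two-cohort
    generator with known clonal ground truth so the whole pipeline can be
    exercised and validated without access to individual-level array data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse
Config/testthat/edition: 3
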