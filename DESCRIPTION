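Package: directomics
Title: Paired Multi-Omics Differential Analysis with Effect-Direction
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for paired pre/post multi-omics cohort
    studies: synthetic cohort simulation with known ground truth,
    presence filtering, K-nearest-neighbour imputation, median and
    quantile normalization, assumption-gated differential testing with
    PLS-DA variable importance in projection (VIP), intersection of
    cross-sectional and longitudinal comparison axes with classification
    of shared molecules into improvement-type and aggravation-type by
    direction concordance, hypergeometric pathway over-representation,
    validation-phase nonparametric statistics, isotope-dilution
    calibration for absolute quantification, and effect-size, power and
    covariate-adjusted sensitivity analyses.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
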