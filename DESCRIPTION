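Package: matesite
Title: Acoustic Telemetry Residency and Reproductive-Cycle Analysis for a
    Shark Mating Site
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for multi-decade monitoring of an
    elasmobranch courtship and mating ground: segmentation of acoustic
    detection streams into visits and arrival-departure presence strings,
    within-season residency metrics and diel profiles, multi-year
    return-interval extraction and biennial/triennial reproductive-cycle
    classification, potential reproductive lifetime output (PRLO)
    projections, and a statistical layer with rank tests, a two-sample
    Anderson-Darling test, and separation-robust Bayesian-regularized
    generalized linear mixed models.  Includes a synthetic detection-history
    generator with known ground truth so every stage can be validated
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    mvtnorm
Suggests:
    testthat (>= 3.0.0),
    lme4,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
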