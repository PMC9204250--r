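Package: stagescreen
Title: Event-Based Disease Progression Modelling for Clinical Trial Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits kernel-density event-based models (KDE-EBM) of cumulative
    cognitive decline from cross-sectional cohort data, assigns maximum-likelihood
    disease stages to individual subjects, and uses those stages to stratify
    clinical-trial participants for subgroup analyses of treatment effect
    (Kaplan-Meier curves, Cox proportional-hazards models with Hochberg
    multiplicity correction, and per-visit Mann-Whitney comparisons of cognition).
    Includes a synthetic-cohort generator with known ground truth (event sequence,
    stages, subgroup hazard ratios) for validating sequence recovery, staging
    accuracy, and subgroup effect detection.
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
    jsonlite,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
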