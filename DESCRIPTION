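Package: metscreen
Title: Obesity- and Lipid-Related Indices for Metabolic Syndrome Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes thirteen obesity- and lipid-related indices (BMI, waist-to-height
    ratio, visceral adiposity index, a body shape index, body roundness index, lipid
    accumulation product, conicity index, Chinese visceral adiposity index, the
    triglyceride-glucose index and its anthropometric combinations), evaluates the
    NCEP ATP III metabolic-syndrome definition with Chinese waist thresholds, derives
    Youden-optimal screening cut-offs with full diagnostic metrics from empirical ROC
    curves, and estimates covariate-adjusted odds ratios for dichotomized indices by
    logistic regression. Ships a calibrated synthetic cohort generator emulating the
    sex-stratified structure of a middle-aged and elderly Chinese population so that
    the whole pipeline is testable without external microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    tools,
    MASS
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
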