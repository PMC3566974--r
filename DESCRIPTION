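Package: cprvalid
Title: Multi-Dataset External Validation of Clinical Prediction Rules for
    Serious Infection in Children
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to validate sign-and-symptom based clinical prediction
    rules and triage guidelines for serious infection in acutely ill
    children across multiple individual-patient datasets. Provides
    executable implementations of a five-stage decision tree, a pneumonia
    rule, a meningitis rule, the Yale Observation Scale, the NICE
    feverish-illness traffic-light system and the Dutch GP (NHG) alarm
    symptoms; proxy-variable resolution and explicit missing-data policies;
    diagnostic-accuracy statistics with exact binomial, Wald and log-method
    confidence intervals; pre/post-test probabilities and dumbbell
    reporting stratified by prevalence setting; dataset-eligibility checks
    and the age-subgroup and reduced-rule sensitivity analyses; and a
    synthetic individual-patient-data generator whose preset profiles
    emulate the printed characteristics of seven European ambulatory-care
    datasets, with closed-form calibration of any-of rules to target
    operating characteristics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
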