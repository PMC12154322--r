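Package: adrisk
Title: Age-Stratified Risk Zoning for Preclinical Alzheimer's Disease
    Biomarkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Models the age-related progression of core Alzheimer's disease
    biomarkers (CSF amyloid-beta 42, amyloid PET, CSF Tau, MRI FDG-PET) with
    logistic (sigmoid) trajectories, computes a composite cognitive-impairment
    (CI) score as an age-scaled exponential plus a weighted sum of biomarker
    terms, and classifies individuals into age-banded Safe, Mild Risk and
    Unsafe zones.  Includes a seeded synthetic cohort generator, cohort CSV
    cleaning and imputation, per-biomarker threshold flagging against
    age-group reference tables, a safe-biomarker-bound solver, a retrospective
    intervention-window estimator, and a configurable command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
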