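Package: pewrisk
Title: Protein-Energy Wasting Risk Scoring and Validation for Hemodialysis Cohorts
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the six-component ordinal risk score for
    protein-energy wasting in maintenance hemodialysis patients (Hashmi's
    tool): banded scoring of body mass index, functional capacity, dialysis
    vintage, serum albumin, serum ferritin and comorbidity count, with
    low/high risk stratification at a configurable threshold. Provides the
    contingency statistics used to validate the score against
    hospitalization and mortality (Pearson chi-square, odds ratios, Woolf
    log-odds confidence intervals, row percentages), ships the aggregate
    validation-cohort counts as packaged fixtures, and includes a synthetic
    cohort generator with a logistic score-to-outcome model so the whole
    pipeline is testable without patient data.
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
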