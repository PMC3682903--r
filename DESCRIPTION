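Package: iavalidate
Title: Validity of Coded Inflammatory Arthritis Diagnoses in Primary Care
    Electronic Medical Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Assesses the positive predictive value of coded inflammatory
    arthritis diagnoses (ICPC-1 rubric L88) in primary-care electronic
    medical records against a chart-review reference standard, and evaluates
    rule-based case-finding algorithms built from three criteria (repeat
    DMARD/biologic prescriptions, contact and prescription volume, age at
    first coded contact) combined with at-least-k-of-n thresholds. Includes
    exact reconstruction of the 8-pattern criterion-by-confirmation joint
    distribution from published marginal count tables via
    inclusion-exclusion, materialization of patient-level fixtures from a
    joint, and a seeded synthetic EMR cohort generator for testing
    case-finding algorithms without access to real records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
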