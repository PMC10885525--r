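Package: phenoppv
Title: Validation of Claims-Based Phenotyping Algorithms by Chart-Review
    Positive Predictive Value
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for validating rule-based computable phenotypes defined
    over longitudinal administrative claims. Builds cohort follow-up under
    enrollment-gap, residency-gap, age and death censoring; adjudicates a
    chart-review gold standard by chronological review of diagnosis-code
    days; expresses claims-based classification algorithms (distinct
    code-day counts, calendar-era windows spanning the ICD-9-CM to
    ICD-10-CM transition, companion procedure-code clauses) as declarative
    specifications; and summarises algorithm performance as positive
    predictive values with Wilson score confidence intervals. Includes a
    synthetic-data generator that emulates an HIV diagnosis-code validation
    study among women health-plan enrollees, with known per-patient ground
    truth, so the full pipeline runs end to end without access to real
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
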