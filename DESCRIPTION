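Package: crcvalidate
Title: Validation of Cancer Surgery Records in Administrative Health Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for validating colorectal cancer surgery records in
    administrative health data (physician billing claims and hospital
    discharge abstracts, alone and combined) against a cancer registry
    treated as the gold standard. Provides cohort inclusion and exclusion
    rules keyed to ICD-O topography and staging, diagnosis-anchored first
    surgery linkage within a configurable day window, the standard
    diagnostic accuracy measures (sensitivity, specificity, positive and
    negative predictive value, observed agreement) with Wilson score
    confidence intervals and instability flags, stratified reporting by
    year, stage and tumor site, a synthetic linked-cohort generator for
    fully reproducible testing, and tools that reconstruct integer 2x2
    contingency tables from published marginal counts and rounded
    whole-percent measures, including exhaustive feasibility audits.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    rlang,
    stats,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
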