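Package: dpquality
Title: Privacy-Preserving Data Quality Assessment for Federated Health Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Patient-level data quality checks over HL7 FHIR R4 resources
    (Patient, Condition, Specimen) whose results are disclosed only after
    perturbation with the Laplace mechanism, under an explicitly accounted
    per-report privacy budget with sequential composition. Includes a
    synthetic cohort generator that injects quality errors at configurable
    rates, a catalogue of nine built-in checks across six quality dimensions
    (accuracy, completeness, consistency, timeliness, validity, uniqueness),
    closed-form utility and disclosure-risk forecasts (noisy-ratio standard
    deviation, stratification variance, Bayesian inclusion-certainty bounds),
    and a simulated agent/server federation that aggregates
    differentially-private reports only.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
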