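Package: dsnboot
Title: Neutropenia Endpoints and Stratified Bootstrap Noninferiority Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives chemotherapy-induced neutropenia endpoints (duration of
    severe neutropenia, time to absolute-neutrophil-count recovery, nadir depth
    and timing, febrile neutropenia) from longitudinal complete-blood-count
    records collected under an adaptive monitoring schedule, and compares arms
    of a granulocyte colony-stimulating-factor trial against an active control
    with a baseline-weight-stratified bootstrap: percentile confidence
    intervals, resampling-based noninferiority and superiority P-values, and a
    fixed-margin decision rule.  Includes a longitudinal ANC trajectory
    simulator with dose-dependent myelosuppression, a fixture cohort that
    reproduces the published Cycle-1 severe-neutropenia distribution of the
    dose-ranging study the pipeline models, and analytic plus simulation-based
    power for the noninferiority design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
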