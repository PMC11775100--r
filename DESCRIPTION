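Package: egfrtraj
Title: Bias-Corrected eGFR Trajectories from Electronic Medical Record Creatinine
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates gold-standard study-center serum creatinine with
    calendar-dated electronic-medical-record (eMR) creatinine to build
    longitudinal kidney-function datasets. Provides quality control of raw
    eMR creatinine, per-calendar-year multiplicative assay-bias estimation
    under a log-scale additive error model (ratio of geometric means),
    proxy correction factors for uncovered years, the race-free CKD-EPI
    2021 eGFR equation and its closed-form inverse, event-aware trajectory
    assembly with censoring after kidney-relevant events, annualized
    eGFR-decline estimation with risk-factor regressions, peri-acute-kidney-
    injury decline, and a synthetic cohort generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stats,
    utils,
    generics,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
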