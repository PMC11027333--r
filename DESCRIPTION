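Package: psadpathways
Title: Risk-Stratified Prostate Biopsy Pathway Evaluation and Decision
    Curve Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates biopsy-selection pathways for suspected prostate
    cancer that combine MRI suspicion scores (PI-RADS) with
    prostate-specific antigen density (PSAD) risk bands. Provides a
    declarative rule engine for diagnostic pathways, patient-level cohort
    handling with CSV import/export, cross-tabulation of clinically
    significant cancer prevalence by PI-RADS group and PSAD band,
    per-pathway outcome summaries (biopsy avoidance, missed significant
    cancer, overdiagnosis of insignificant cancer), Pearson chi-square
    pathway comparisons, and decision-curve analysis with net-benefit
    curves, closed-form crossover thresholds and dominance intervals. A
    calibrated synthetic-cohort generator reproduces a published
    2055-patient contingency structure exactly and supplies a seeded
    stochastic sampler for simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
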