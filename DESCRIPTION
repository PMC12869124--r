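Package: stratcohort
Title: Privacy-Aware Stratified Construction of Representative Cancer
    Sample Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds nationally representative cancer sample cohorts from a
    registry-shaped population by stratified random sampling with
    proportional allocation, enforcing a representativeness criterion based
    on the finite-population-correction 95% confidence interval for the
    stratum mean of annual medical costs, with candidate resampling,
    closest-mean selection and incremental sample-size augmentation.
    Includes small-cell suppression for privacy, a seeded synthetic
    cancer-registry generator calibrated to published cohort marginals, and
    a survival validation suite (one-sample log-rank tests against the
    stratum reference population, Kaplan-Meier comparison, follow-up and
    cost summaries).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    tibble,
    dplyr,
    rlang
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
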