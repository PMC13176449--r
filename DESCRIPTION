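Package: glp1traj
Title: Weight-Trajectory Phenotyping for GLP-1 Receptor Agonist Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for real-world analysis of weight-loss response to
    glucagon-like peptide-1 receptor agonist (GLP-1RA) therapy from
    longitudinal electronic-health-record style tables. Implements an
    eligibility funnel with index-date and baseline-weight derivation,
    four-way first-year trajectory classification (super, moderate,
    minimal, regainer), windowed population trajectory curves with
    Savitzky-Golay smoothing, brand-stratified contingency statistics
    (Wilson intervals, Wald odds ratios, chi-square tests), age/sex
    propensity-score greedy caliper matching with balance diagnostics,
    and a phenome-wide pre-treatment disease prevalence screen with
    rate ratios and Benjamini-Hochberg false-discovery-rate control.
    Includes a synthetic EHR cohort generator with planted latent
    response classes and disease enrichments so every pipeline stage is
    testable without access to protected patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    lubridate,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
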