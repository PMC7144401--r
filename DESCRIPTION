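Package: vigilr
Title: EEG Vigilance Staging, Arousal Metrics, and Sleepiness Association Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the relationship between subjective
    (questionnaire-based) and objective (resting-state EEG based) sleepiness.
    Implements a transparent seven-stage EEG-vigilance classifier for
    eyes-closed resting recordings (1-second resolution, spectral power and
    alpha topography cascade with slow-eye-movement, sleep-spindle and
    K-complex detectors), arousal-regulation summaries (stage-time
    proportions, mean vigilance value, arousal stability score), scoring of
    standard sleepiness instruments (ESS, KSS, SSS, VAS, SF-A restedness),
    and a statistical battery linking the two domains: rank tests,
    Spearman correlations, Fisher-z correlation-difference tests, canonical
    correlation with a bootstrap Pillai-Bartlett trace test, and Gaussian and
    proportional-odds interaction regressions.  A seeded synthetic-cohort
    generator produces questionnaire tables and multichannel EEG/EOG
    recordings driven by a latent sleepiness trait for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
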