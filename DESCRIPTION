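Package: sleepmood
Title: Day-Level Causal Analysis of Coupled Sleep and Mood Diaries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the day-to-day interplay between self-reported
    sleep quality and mood from ecological momentary assessment (EMA) diaries.
    Builds directional lagged day pairs from long-format daily panels, applies
    within-person z-score normalization, estimates population cross-effects with
    linear mixed-effects models, and estimates per-subject "personal causal
    effects" by propensity-score matching day-level treatment and control days
    within each subject, with bootstrap inference over subjects, history-depth
    sweeps, and symptom-group contrasts. Includes a synthetic EMA-cohort
    generator with known cross-lagged ground truth, subject reporting styles,
    shared daily confounding, and missingness, so the full pipeline can be
    validated against simulated truth.
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
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
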