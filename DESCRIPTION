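Package: effortsens
Title: Perceived-Effort Sensitivity Analysis for Grip Force-Matching Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis tools for effort-psychophysics
    experiments in which participants squeeze a hand dynamometer to match
    target forces (as fractions of maximal voluntary contraction) and rate
    their perceived effort on a 0-100 visual-analogue scale. Provides a
    synthetic-cohort generator emulating the task design, including
    force-trace simulation with signal-dependent motor noise; preprocessing
    with cross-hand MVC recalibration and participant exclusion rules;
    force-trace feature extraction (area under the curve, coefficient of
    variation, initial overshoot, excess force, cumulative force); selection
    of the force-to-rating link function by BIC over linear mixed-effects
    models; per-participant Huber robust regression estimating force and
    failure sensitivity with second-level symptom-association models under
    false-discovery-rate control; and a two-step Huber-weighted,
    cross-validated ridge regression weighting all trial features.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
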