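Package: rjapupil
Title: Gaze-Following and Pupillometry Analysis of Reactive Joint Attention
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for eye-tracking studies of reactive
    joint attention (RJA) in preschoolers. Cleans raw 300 Hz binocular
    gaze and pupil streams (blink correction, plausibility filters,
    Savitzky-Golay smoothing), detects saccades with an adaptive
    data-driven velocity threshold, classifies fixations, scores per-trial
    RJA from area-of-interest fixation sequences, and derives baseline
    pupil size (BPS) and the stimulus-evoked pupillary response (SEPR).
    An inference layer fits binomial and Gaussian mixed models with
    crossed random intercepts, marginal odds-ratio contrasts with cluster
    bootstrap intervals, Nakagawa R-squared, cascade linear models,
    dropout ANOVA with noncentral-F power, and quasi-Bayesian causal
    mediation (ACME/ADE). A paradigm-faithful synthetic-session generator
    with known ground truth supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    generics,
    ggplot2,
    lme4,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
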