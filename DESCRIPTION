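Package: pupgrowth
Title: Growth-Standard z-Scores, Centile Crossings and Trajectory Models
    for Canine Weight Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for validating canine weight-for-age growth standards
    against longitudinal bodyweight records. Converts weights to
    z-scores through an LMS (Box-Cox power, median, coefficient of
    variation) representation of sex- and size-class-specific standards,
    cleans cohorts with a binned box-whisker procedure with
    loess-smoothed outlier bounds plus individual-trajectory rules,
    enumerates per-dog centile-line crossings against the nine-centile
    chart, fits population median z-score trajectories with a
    penalized B-spline scaled-t model selected by the Schwarz Bayes
    Criterion, provides worm-plot and Q-statistic fit diagnostics, and
    compares groups with random-intercept mixed models and
    Tukey-adjusted contrasts. A synthetic-cohort generator reproduces
    the longitudinal structure these analyses assume, so the whole
    pipeline is testable without proprietary clinic or colony data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    tibble,
    dplyr,
    jsonlite,
    lme4,
    lmerTest,
    emmeans
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    withr
Config/testthat/edition: 3
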