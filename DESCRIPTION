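Package: stepgoals
Title: Step-Goal Personalization and Matched Difference-in-Differences Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for adaptive daily step-goal assignment in mobile health
    apps (a moving-window percentile-rank algorithm with self-set and default
    routes) and for the causal evaluation of goal personalization on weekly
    step counts: seeded synthetic cohort and panel generation with
    self-selection into personalization, data cleaning (group-mean age
    imputation, unknown-gender coding, system-error outlier replacement),
    baseline-activity classification, propensity-score estimation with 1:1
    greedy nearest-neighbour matching and covariate balance diagnostics, a
    two-way fixed-effects within estimator of the difference-in-differences
    model with heteroskedasticity-robust or cluster-robust standard errors, an
    event-study test of the parallel-trends assumption, and heterogeneity
    analysis on activity-class subsamples.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    knitr,
    rmarkdown,
    sandwich,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
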