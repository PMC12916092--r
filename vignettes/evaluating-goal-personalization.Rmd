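---
title: "Evaluating step-goal personalization with matched difference-in-differences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating step-goal personalization with matched difference-in-differences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stepgoals)
```

## The evaluation problem

In a mobile health app, every user starts with the same default goal of
2000 steps per day on at least 5 days per week. Users invited by email can
answer a survey about that goal and then either set their own daily goal,
accept a goal computed by an adaptive algorithm, or keep the default. Because
users *choose* whether to respond and whether to personalize, the groups are
self-selected: users who personalize walk far more at baseline than users who
never respond. A raw post-period comparison would mostly measure that
selection, not the effect of personalization.

`stepgoals` implements the full evaluation chain for this design:

1. a **goal engine** reproducing the app's assignment rules,
2. a **synthetic cohort generator** with known (injected) treatment effects,
3. **cleaning** of the raw weekly panel,
4. **propensity-score matching** of each personalization group to comparable
   non-personalizing users,
5. a **two-way fixed-effects difference-in-differences (DID) estimator** with
   robust standard errors and an event-study check of parallel trends,
6. **heterogeneity analysis** on baseline-activity classes.

## The goal engine

The algorithmic route takes the user's daily step counts from the four weeks
before the survey. With at least 7 observations, it sorts them and picks the
observation at rank `select_rank(n)` — one position below the median — so
that the target is attainable on an ordinary day yet above lazy days:

```{r}
select_rank(28)
select_rank(7)
```

The selected value is rounded half-up to the nearest 100 steps and clamped to
[2000, 8000]:

```{r}
algorithm_goal(rep(9000, 28), "too_low")
```

With fewer than 7 observations the algorithm falls back on the survey answer
alone: 1500 steps per day if the default felt *too high*, 3500 if it felt
*too low*. Self-set goals are validated against the app's [1000, 20000]
range, and everyone else keeps `default_goal()`.

## The synthetic cohort

Real deployment data are proprietary, so the package validates its estimator
chain on a generator with known truth. The weekly outcome follows the same
model the estimator assumes,

$$ y_{it} = \theta_i + \lambda_t + \beta_i\,\mathrm{personalization}_{it} + \varepsilon_{it}, $$

with a log-normal individual level $\theta_i$, common week effects
$\lambda_t$, treatment switched on from week 8 for all survey responders,
and class-specific injected effects $\beta_i$.

Three generator choices matter for interpreting the results; each is a
deliberate modelling decision, not a tuning knob:

* **Selection on observables by construction.** Weeks 6 and 7 are realized
  *before* group assignment, and the logistic selection into responding and
  personalizing depends on the data only through the observed weeks-6–7
  total (plus usage duration). Treatment assignment is therefore ignorable
  given the matching covariates. Had selection acted on the latent level
  $\theta_i$ instead, matching on the noisy realized baselines would regress
  to the mean and bias even a zero effect — a failure of the *design*, which
  no estimator downstream could repair.
* **Dispersion grows with activity.** The per-user noise SD is
  `noise_sd * sqrt(theta / noise_reference)`, i.e. variance proportional to
  the level, as with overdispersed counts. A level-independent SD sized for
  the high-activity personalizers would exceed a typical user's entire
  weekly total and make the truncation of step counts at zero a first-order
  feature of the data.
* **Defaults mirror the deployment.** Group sizes (230 self-set, 236
  algorithm, 933 default-keeping responders, 1999 never-emailed, the rest
  non-responders out of 5800), covariate distributions and the strength of
  self-selection are calibrated so that the simulated group summaries —
  including a week-6 standardized mean difference of about 1.3 between
  personalizers and non-responders — are of the magnitude the evaluation has
  to cope with.

## Matching and estimation conventions

* **Propensity model**: logistic regression of treatment-group membership on
  seven covariates (age, gender, app usage duration, weeks-6/7 steps,
  weeks-6/7 days-goal-achieved), fitted separately per comparison.
* **Matching**: greedy 1:1 nearest neighbour on the probability scale,
  without replacement, treated users processed in descending score order,
  ties broken by smaller user id, no caliper by default.
* **Balance**: standardized mean differences use the **treated-group SD** as
  denominator (`denominator = "pooled"` gives the symmetric convention).
* **Activity classes**: within-group quartiles of the weeks-6+7 step total;
  Q1 is *low*, Q2–Q3 *medium*, Q4 *high*; values at a cut point fall to the
  lower class.
* **DID**: the within estimator (double demeaning), numerically identical to
  OLS with individual and week dummies; HC1 or individual-clustered CR1
  standard errors, with the absorbed fixed effects counted among the model
  parameters in the degrees-of-freedom correction.
* **Parallel trends**: `event_study()` replaces the single treatment term by
  treated-by-week interactions with week 7 as reference; the week-6
  coefficient is the pre-trend probe.

## What the Monte-Carlo suites check — and at what scale

The test suite validates the chain by parameter recovery, type-I error and
detector power. These suites run the treated groups at quarter scale
(58/59/233) but give the matching stage a *large* never-emailed pool (2000
users, about 11 pool candidates per treated user of the biggest group).

That pool size is deliberate. Greedy matching without replacement needs
common support: once the closest controls are used up, later treated users
receive increasingly distant matches. At the deployment's own proportions
the 933 default-keeping responders face only about 4.7 candidates each, and
the resulting match discrepancy — a real feature of the design, not an
estimator defect — shifts that group's estimate by one to two hundred weekly
steps. The recovery suites therefore isolate estimator behaviour with an
ample pool, while the pipeline tests document that the restricted
`pool = "no_response"` robustness re-run is the setting where the small
reminder effect is hardest to establish.

## Running the pipeline

```{r, eval = FALSE}
bundle <- run_full(run_config(sim = simulation_config(seed = 1)))
bundle$main_table       # one matched DID estimate per strategy
bundle$event_study      # pre-trend and dynamic-effect coefficients
bundle$heterogeneity    # class-specific effects per strategy
```

Every number in the bundle is reproducible from the configuration and seed
alone; running the same configuration twice yields byte-identical output
files, and `run_config_from_yaml()` drives the same pipeline from a YAML
file. An external panel CSV can replace the simulation via
`run_config(panel_path = ...)`, in which case quantities that require
generator truth (goal-level comparisons) are omitted.
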