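#' Simulate a cohort of app users with self-selection into personalization
#'
#' Draws user covariates (age, gender, app usage duration) and a log-normal
#' latent baseline weekly step count (the individual effect), then assigns
#' group labels in three stages that mirror the deployment: a random
#' never-emailed subset (`group2`); logistic self-selection of survey
#' responders on the standardized log realized weeks-6--7 baseline and usage
#' duration (weight `selection_strength`); and, among responders, logistic
#' sorting of higher-baseline users into the two personalization groups, the
#' remainder keeping the default goal (`not_changed`). Week-6 and week-7
#' outcomes are realized before group assignment, so selection depends on
#' the data only through the observed pre-period measurements (the same
#' quantities matching later conditions on), and each user's baseline
#' activity class (within-group quartiles of the week-6 + week-7 total: Q1
#' low, Q2--Q3 medium, Q4 high) and class-conditional assigned goal are part
#' of the generated truth.
#'
#' Deterministic given `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return A tibble with one row per user: `user_id`, `group`, `age` (may be
#'   `NA`), `gender` (may be `NA`), `usage_days`, `theta` (latent expected
#'   weekly steps), `steps_week6`, `steps_week7`, `activity_class`, `survey`
#'   (`too_high`/`too_low`/`all_right`/`NA`), `goal_daily_steps`,
#'   `goal_method`, `effect` (the user's true weekly-step treatment effect).
#' @export
simulate_users <- function(config) {
  validate_sim_config(config)
  withr::with_seed(as.integer(config$seed), simulate_users_impl(config))
}

simulate_users_impl <- function(cfg) {
  n <- cfg$n_users
  sizes <- cfg$group_sizes
  n_resp <- sizes[["personalized_by_you"]] +
    sizes[["personalized_by_algorithm"]] + sizes[["not_changed"]]
  n_group1 <- n - sizes[["group2"]]
  if (n_resp > n_group1) {
    stop_input("responder groups (%d) exceed the emailed group (%d)",
               n_resp, n_group1)
  }

  age <- round(stats::rnorm(n, cfg$age_mean, cfg$age_sd))
  age <- pmax(age, 18)
  gender <- sample(names(cfg$gender_probs), n, replace = TRUE,
                   prob = cfg$gender_probs)
  usage <- pmax(round(stats::rnorm(n, cfg$usage_mean, cfg$usage_sd)), 28)
  theta <- stats::rlnorm(n, cfg$baseline_log_mean, cfg$baseline_log_sd)

  # weeks 6-7 are realized before group assignment: self-selection acts on
  # the baseline activity users (and the survey) actually observe, so that
  # treatment assignment depends on the data only through the same pre-period
  # measurements the matching stage later conditions on (selection on
  # observables by construction; selecting on the latent mean instead would
  # make matching on the noisy realized baselines regress to the mean)
  sd_i <- noise_sd_by_user(theta, cfg)
  w6 <- pmax(theta + cfg$week_effects[1] + stats::rnorm(n, 0, sd_i), 0)
  w7 <- pmax(theta + cfg$week_effects[2] + stats::rnorm(n, 0, sd_i), 0)

  z_b <- as.numeric(scale(w6 + w7))
  z_u <- as.numeric(scale(usage))

  ids <- seq_len(n)
  group <- rep(NA_character_, n)
  g2 <- sample(ids, sizes[["group2"]])
  group[g2] <- "group2"
  group1 <- setdiff(ids, g2)

  w_resp <- stats::plogis(cfg$selection_intercept +
                            cfg$selection_strength * z_b[group1] +
                            cfg$usage_weight * z_u[group1])
  responders <- group1[resample_weighted(length(group1), n_resp, w_resp)]
  group[setdiff(group1, responders)] <- "no_response"

  n_pers <- sizes[["personalized_by_you"]] +
    sizes[["personalized_by_algorithm"]]
  w_pers <- stats::plogis(cfg$personalize_strength * z_b[responders])
  personalizers <- responders[resample_weighted(length(responders), n_pers, w_pers)]
  group[setdiff(responders, personalizers)] <- "not_changed"
  you <- sample(personalizers, sizes[["personalized_by_you"]])
  group[you] <- "personalized_by_you"
  group[setdiff(personalizers, you)] <- "personalized_by_algorithm"

  cls <- rep(NA_character_, n)
  for (g in unique(group)) {
    in_g <- which(group == g)
    cls[in_g] <- quartile_classes(w6[in_g] + w7[in_g])
  }

  survey <- rep(NA_character_, n)
  survey[group == "not_changed"] <- "all_right"
  pers <- group %in% c("personalized_by_you", "personalized_by_algorithm")
  p_low <- stats::plogis((theta[pers] / 7 - 2000) / 1000)
  survey[pers] <- ifelse(stats::runif(sum(pers)) < p_low,
                         "too_low", "too_high")

  goal <- rep(2000L, n)
  method <- rep("default", n)
  is_you <- group == "personalized_by_you"
  goal[is_you] <- draw_goals(cls[is_you], cfg$goal_mean_by_class$self_set,
                             cfg$goal_sd, 1000, 20000)
  method[is_you] <- "self_set"
  is_alg <- group == "personalized_by_algorithm"
  goal[is_alg] <- draw_goals(cls[is_alg], cfg$goal_mean_by_class$algorithm,
                             cfg$goal_sd, 2000, 8000)
  method[is_alg] <- "algorithm"

  effect <- rep(0, n)
  effect[is_you] <- cfg$effect_by_class$personalized_by_you[cls[is_you]]
  effect[is_alg] <- cfg$effect_by_class$personalized_by_algorithm[cls[is_alg]]
  effect[group == "not_changed"] <- cfg$effect_not_changed

  age[stats::runif(n) < cfg$missing_age_frac] <- NA
  gender[stats::runif(n) < cfg$missing_gender_frac] <- NA

  tibble::tibble(
    user_id = ids, group = group, age = age, gender = gender,
    usage_days = usage, theta = theta,
    steps_week6 = w6, steps_week7 = w7,
    activity_class = cls, survey = survey,
    goal_daily_steps = goal, goal_method = method, effect = effect
  )
}

# weighted sampling without replacement of k indices out of n
resample_weighted <- function(n, k, w) {
  if (all(w == w[1])) sample.int(n, k) else sample.int(n, k, prob = w)
}

# Per-user weekly noise SD. The default is proportional to the individual
# level: sd_i = noise_sd * theta_i / noise_reference, i.e. `noise_sd` is the
# weekly SD at the reference activity level (the scale of the matched,
# high-activity users). Step counts are non-negative with dispersion that
# grows with activity; a level-independent SD sized for the high-activity
# users would exceed the typical user's entire weekly total and make the
# zero-truncation a first-order feature of the data.
noise_sd_by_user <- function(theta, cfg) {
  if (isTRUE(cfg$heteroskedastic)) {
    cfg$noise_sd * sqrt(theta / cfg$noise_reference)
  } else {
    rep(cfg$noise_sd, length(theta))
  }
}

# Q1 -> low, Q2-Q3 -> medium, Q4 -> high; cut points are the empirical
# 25th/75th percentiles (linear interpolation), values at a cut point fall
# to the lower class; fully tied input degenerates to all-medium.
quartile_classes <- function(total) {
  if (length(unique(total)) == 1L) return(rep("medium", length(total)))
  q <- stats::quantile(total, c(0.25, 0.75), names = FALSE, type = 7)
  ifelse(total <= q[1], "low", ifelse(total <= q[2], "medium", "high"))
}

draw_goals <- function(cls, means, sd, lo, hi) {
  raw <- stats::rnorm(length(cls), means[cls], sd)
  as.integer(clamp(round_half_up(raw, 100), lo, hi))
}

#' Simulate the user-week panel (weeks 6--11)
#'
#' Builds the weekly outcome
#' `steps = theta_i + lambda_t + effect_i * personalization_it + eps_it`
#' (truncated at zero), where `personalization_it` is 1 for users in any of
#' the three responder groups from week 8 on and 0 otherwise; weeks 6 and 7
#' reuse the outcomes realized in [simulate_users()] (goal assignment and
#' activity classification happen after those weeks). Days-goal-achieved is
#' drawn as a binomial over 7 days whose success probability increases with
#' the week's steps relative to the user's current weekly goal. System-error
#' outlier weeks and the configured missingness are injected at the
#' configured rates. A non-zero `pretrend_shift` displaces treated users'
#' week-6 outcome, breaking parallel trends for detector testing.
#'
#' @param users Output of [simulate_users()].
#' @param config The same [simulation_config()].
#' @return A tibble with `6 * nrow(users)` rows: `user_id`, `week` (6--11),
#'   `weekly_steps`, `personalization`, `days_goal_achieved`, `group`,
#'   `age`, `gender`, `usage_days`.
#' @export
simulate_panel <- function(users, config) {
  validate_sim_config(config)
  assert_columns(users, c("user_id", "group", "theta", "steps_week6",
                          "steps_week7", "goal_daily_steps", "effect"),
                 "users")
  panel_seed <- as.integer((as.numeric(config$seed) + 1) %% 2147483647)
  withr::with_seed(panel_seed, simulate_panel_impl(users, config))
}

simulate_panel_impl <- function(users, cfg) {
  n <- nrow(users)
  weeks <- 6:11
  treated <- users$group %in% c("personalized_by_you",
                                "personalized_by_algorithm", "not_changed")
  sd_i <- noise_sd_by_user(users$theta, cfg)

  rows <- lapply(seq_along(weeks), function(j) {
    w <- weeks[j]
    post <- w >= 8
    if (w == 6) {
      y <- users$steps_week6 + ifelse(treated, cfg$pretrend_shift, 0)
    } else if (w == 7) {
      y <- users$steps_week7
    } else {
      y <- pmax(users$theta + cfg$week_effects[j] +
                  ifelse(treated, users$effect, 0) +
                  stats::rnorm(n, 0, sd_i), 0)
    }
    goal_w <- ifelse(post & treated, users$goal_daily_steps, 2000)
    ratio <- y / (7 * goal_w)
    days <- stats::rbinom(n, 7, stats::plogis(1.5 * ratio - 2.2))
    tibble::tibble(
      user_id = users$user_id, week = w, weekly_steps = y,
      personalization = as.integer(post & treated),
      days_goal_achieved = days, group = users$group,
      age = users$age, gender = users$gender, usage_days = users$usage_days
    )
  })
  panel <- dplyr::bind_rows(rows)
  out <- stats::runif(nrow(panel)) < cfg$outlier_frac
  panel$weekly_steps[out] <- cfg$outlier_value
  dplyr::arrange(panel, .data$user_id, .data$week)
}

#' Simulate a full cohort and its panel in one call
#'
#' @inheritParams simulate_users
#' @return A list with elements `users` and `panel`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  users <- simulate_users(config)
  list(users = users, panel = simulate_panel(users, config))
}
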