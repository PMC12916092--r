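#' Simulation configuration for a synthetic personalization cohort
#'
#' Bundles every parameter of the synthetic cohort and panel generator. The
#' defaults reproduce the study conditions of the field deployment the
#' package models: 5800 app users, of whom 230 personalize their goal
#' themselves, 236 have it set by the algorithm, 933 respond but keep the
#' default, 1999 form a never-emailed random group and the rest do not
#' respond; strong self-selection of high-baseline users into responding and
#' personalizing; weekly panels over calendar weeks 6--11 with individual and
#' week effects; treatment switched on from week 8 with activity-class
#' heterogeneity; and the raw-data anomalies the cleaning stage removes
#' (missing age/gender, system-error outlier weeks).
#'
#' @param n_users Total cohort size.
#' @param group_sizes Named integer vector with entries
#'   `personalized_by_you`, `personalized_by_algorithm`, `not_changed`,
#'   `group2`. The remainder of the emailed group becomes `no_response`.
#' @param age_mean,age_sd Age distribution (years).
#' @param gender_probs Named probabilities over `woman`, `man`, `unknown`.
#' @param usage_mean,usage_sd App-membership duration (days; truncated at 28).
#' @param baseline_log_mean,baseline_log_sd Log-normal parameters of the
#'   latent expected weekly step count (the individual effect).
#' @param selection_intercept,selection_strength,usage_weight Logistic
#'   selection of survey responders on the standardized log baseline and
#'   standardized usage duration; `selection_strength = 0` removes
#'   self-selection.
#' @param personalize_strength Logistic weight with which responders with
#'   higher baselines sort into the two personalization groups rather than
#'   keeping the default goal.
#' @param week_effects Numeric length-6 vector of common week effects for
#'   weeks 6--11 (the same for every group, honouring parallel trends).
#' @param effect_by_class Named list with elements `personalized_by_you` and
#'   `personalized_by_algorithm`, each a named vector of weekly-step
#'   treatment effects for classes `low`, `medium`, `high`.
#' @param effect_not_changed Weekly-step effect for survey responders who
#'   kept the default goal (a reminder effect, constant across classes).
#' @param noise_sd Within-user weekly noise SD (weekly steps) at the
#'   reference activity level; draws are truncated at zero.
#' @param heteroskedastic If `TRUE` (the default), each user's noise SD is
#'   proportional to their baseline, `noise_sd * theta / noise_reference`,
#'   so dispersion grows with activity level as step counts do; `FALSE`
#'   applies `noise_sd` to every user regardless of level.
#' @param noise_reference Activity level (weekly steps) at which the noise
#'   SD equals `noise_sd`; set near the matched high-activity users' scale.
#' @param pretrend_shift Weekly steps added to treated users' week-6 outcome,
#'   breaking parallel trends; 0 (the default) keeps them.
#' @param goal_mean_by_class,goal_sd Class-conditional means (and common SD)
#'   of assigned daily goals for the self-set and algorithm routes.
#' @param missing_age_frac,missing_gender_frac,outlier_frac Anomaly rates.
#' @param outlier_value Weekly steps recorded for a system-error week.
#' @param seed Integer seed; every generator draw derives from it.
#' @return A validated list of class `sim_config`.
#' @export
simulation_config <- function(
    n_users = 5800,
    group_sizes = c(personalized_by_you = 230,
                    personalized_by_algorithm = 236,
                    not_changed = 933,
                    group2 = 1999),
    age_mean = 54.86, age_sd = 10.42,
    gender_probs = c(woman = 0.60, man = 0.28, unknown = 0.12),
    usage_mean = 813.77, usage_sd = 536.42,
    baseline_log_mean = 9.50, baseline_log_sd = 1.00,
    selection_intercept = -4, selection_strength = 3.0, usage_weight = 0.3,
    personalize_strength = 0.8,
    week_effects = c(0, 100, 200, 300, 400, 500),
    effect_by_class = list(
      personalized_by_you = c(low = 383.641, medium = 5841.661,
                              high = 4266.063),
      personalized_by_algorithm = c(low = 5093.521, medium = 5278.006,
                                    high = 1446.37)),
    effect_not_changed = 1758.642,
    noise_sd = 12500,
    heteroskedastic = TRUE,
    noise_reference = 40000,
    pretrend_shift = 0,
    goal_mean_by_class = list(
      self_set = c(low = 3730, medium = 4800, high = 5700),
      algorithm = c(low = 2844, medium = 5200, high = 7061)),
    goal_sd = 400,
    missing_age_frac = 0.05, missing_gender_frac = 0.03,
    outlier_frac = 0.001, outlier_value = 2.5e7,
    seed = 20230220) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  need <- c("personalized_by_you", "personalized_by_algorithm",
            "not_changed", "group2")
  if (!all(need %in% names(cfg$group_sizes))) {
    stop_input("group_sizes must name: %s", paste(need, collapse = ", "))
  }
  if (sum(cfg$group_sizes) > cfg$n_users) {
    stop_input("group sizes sum to %d, exceeding n_users = %d",
               sum(cfg$group_sizes), cfg$n_users)
  }
  probs <- c(cfg$gender_probs, cfg$missing_age_frac, cfg$missing_gender_frac,
             cfg$outlier_frac)
  if (any(probs < 0 | probs > 1)) stop_input("probabilities must lie in [0, 1]")
  if (abs(sum(cfg$gender_probs) - 1) > 1e-8) {
    stop_input("gender_probs must sum to 1")
  }
  if (cfg$noise_sd <= 0) stop_input("noise_sd must be positive")
  if (cfg$noise_reference <= 0) stop_input("noise_reference must be positive")
  if (length(cfg$week_effects) != 6) {
    stop_input("week_effects must have length 6 (weeks 6..11)")
  }
  for (g in c("personalized_by_you", "personalized_by_algorithm")) {
    if (!all(c("low", "medium", "high") %in% names(cfg$effect_by_class[[g]]))) {
      stop_input("effect_by_class$%s must name low, medium, high", g)
    }
  }
  if (length(cfg$seed) != 1 || is.na(cfg$seed)) stop_input("seed must be a single integer")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  users: %d (%s; no_response = %d)\n", x$n_users,
              paste(sprintf("%s = %d", names(x$group_sizes), x$group_sizes),
                    collapse = ", "),
              x$n_users - sum(x$group_sizes)))
  cat(sprintf("  baseline: lognormal(%.2f, %.2f), selection strength %.2f\n",
              x$baseline_log_mean, x$baseline_log_sd, x$selection_strength))
  cat(sprintf("  noise_sd: %.0f, seed: %d\n", x$noise_sd, as.integer(x$seed)))
  invisible(x)
}
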