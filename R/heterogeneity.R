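#' Re-estimate the personalization effect on activity-class subsamples
#'
#' Runs the two-way fixed-effects estimator separately on the low-, medium-
#' and high-active subsamples of one matched comparison. Matched controls
#' inherit the activity class of their treated partner, so each subsample
#' remains a valid matched panel and every pair appears in exactly one
#' class.
#'
#' @param panel A cleaned panel tibble.
#' @param match The [match_nearest_neighbor()] result for the comparison.
#' @param classes A tibble `user_id`, `activity_class` from
#'   [classify_activity()] covering every treated user of the comparison.
#' @param se Passed to [estimate_did()].
#' @return A tibble of class `heterogeneity_result`, one row per class:
#'   `activity_class`, `beta1`, `se`, `t_stat`, `p_value`, `n_obs`,
#'   `n_individuals`, `n_pairs`.
#' @export
estimate_by_class <- function(panel, match, classes,
                              se = c("hc1", "cluster")) {
  se <- match.arg(se)
  stopifnot(inherits(match, "match_result"))
  assert_columns(classes, c("user_id", "activity_class"), "classes")
  pairs <- match$pairs
  cls <- classes$activity_class[base::match(pairs$treated_id,
                                            classes$user_id)]
  if (anyNA(cls)) {
    stop_input("every treated user must have an activity class")
  }
  est_panel <- build_did_panel(panel, match)
  levels_present <- intersect(c("low", "medium", "high"), unique(cls))
  rows <- lapply(levels_present, function(k) {
    in_k <- cls == k
    if (sum(in_k) < 2) {
      stop_input("class '%s' has fewer than 2 matched pairs", k)
    }
    keep <- est_panel$pair_id %in% which(in_k)
    est <- estimate_did(est_panel[keep, ], se = se)
    tibble::tibble(activity_class = k, beta1 = est$beta1, se = est$se,
                   t_stat = est$t_stat, p_value = est$p_value,
                   n_obs = est$n_obs, n_individuals = est$n_individuals,
                   n_pairs = sum(in_k))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("heterogeneity_result", class(out))
  out
}

#' Compare the daily goal levels chosen under two strategies
#'
#' Welch two-sample t-test on assigned daily goals, as used to contrast the
#' goals self-set users choose with the goals the algorithm assigns within
#' an activity class.
#'
#' @param goals_a,goals_b Numeric vectors of assigned daily goals (at least
#'   2 values each).
#' @return A list with `mean_a`, `mean_b`, `t_stat`, `p_value`, `df`.
#' @export
compare_goal_levels <- function(goals_a, goals_b) {
  if (length(goals_a) < 2 || length(goals_b) < 2) {
    stop_input("both samples need at least 2 goals")
  }
  if (stats::sd(goals_a) == 0 && stats::sd(goals_b) == 0) {
    equal <- mean(goals_a) == mean(goals_b)
    return(list(mean_a = mean(goals_a), mean_b = mean(goals_b),
                t_stat = if (equal) 0 else sign(mean(goals_a) - mean(goals_b)) * Inf,
                p_value = if (equal) 1 else 0, df = NA_real_))
  }
  tt <- stats::t.test(goals_a, goals_b, var.equal = FALSE)
  list(mean_a = mean(goals_a), mean_b = mean(goals_b),
       t_stat = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter))
}

#' Compare a personalization effect with the not-changed (reminder) effect
#'
#' Tests whether a personalization strategy raised activity beyond the pure
#' survey-reminder effect observed in responders who kept the default goal.
#' Same statistic as [compare_effects()].
#'
#' @param est_personalized,est_not_changed Two [estimate_did()] results.
#' @return A list with `difference`, `t_stat`, `p_value`.
#' @export
compare_to_not_changed <- function(est_personalized, est_not_changed) {
  compare_effects(est_personalized, est_not_changed)
}
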