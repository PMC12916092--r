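#' Write / read a user-week panel as CSV
#'
#' The on-disk format is plain CSV with one row per user-week, missing values
#' encoded as empty cells. `read_panel()` validates the structural invariants
#' of a weeks-6--11 panel: non-negative step counts, exactly 6 rows per user,
#' and no personalization before week 8.
#'
#' @param panel A panel tibble as produced by [simulate_panel()].
#' @param path File path.
#' @return `read_panel()` returns the panel tibble; `write_panel()` returns
#'   `path` invisibly.
#' @export
write_panel <- function(panel, path) {
  assert_columns(panel, c("user_id", "week", "weekly_steps",
                          "personalization", "days_goal_achieved", "group"),
                 "panel")
  readr::write_csv(panel, path, na = "")
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  panel <- readr::read_csv(path, na = "", show_col_types = FALSE,
                           progress = FALSE)
  assert_columns(panel, c("user_id", "week", "weekly_steps",
                          "personalization", "days_goal_achieved", "group"),
                 "panel file")
  bad <- which(is.na(panel$weekly_steps) | panel$weekly_steps < 0)
  if (length(bad) > 0) {
    stop_input("invalid weekly_steps at data line %d (negative or missing)",
               bad[1] + 1L)
  }
  counts <- table(panel$user_id)
  if (any(counts != 6)) {
    uid <- names(counts)[counts != 6][1]
    stop_input("user %s has %d rows; a weeks-6..11 panel requires exactly 6",
               uid, as.integer(counts[counts != 6][1]))
  }
  if (any(panel$personalization == 1 & panel$week < 8)) {
    stop_input("personalization must be 0 before week 8")
  }
  panel
}

#' Collapse a panel to one row per user with matching covariates
#'
#' Produces the user-level table on which the propensity model is estimated:
#' demographics plus the pre-treatment step totals and goal-achievement
#' counts of weeks 6 and 7.
#'
#' @param panel A cleaned panel tibble (see [clean_panel()]).
#' @return A tibble with columns `user_id`, `group`, `age`, `gender`,
#'   `usage_days`, `steps_week6`, `steps_week7`, `days_achieved_week6`,
#'   `days_achieved_week7`.
#' @export
user_covariates <- function(panel) {
  assert_columns(panel, c("user_id", "week", "weekly_steps",
                          "days_goal_achieved", "group", "age", "gender",
                          "usage_days"), "panel")
  pre <- dplyr::filter(panel, .data$week %in% c(6, 7))
  wide <- tidyr::pivot_wider(
    pre,
    id_cols = c("user_id", "group", "age", "gender", "usage_days"),
    names_from = "week",
    values_from = c("weekly_steps", "days_goal_achieved")
  )
  dplyr::rename(wide,
    steps_week6 = "weekly_steps_6", steps_week7 = "weekly_steps_7",
    days_achieved_week6 = "days_goal_achieved_6",
    days_achieved_week7 = "days_goal_achieved_7")
}
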