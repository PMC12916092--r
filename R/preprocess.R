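#' Impute missing ages with group means
#'
#' Each missing age is replaced by the mean age of the user's group computed
#' over the non-missing ages; non-missing ages are unchanged. Idempotent.
#'
#' @param panel A panel or user tibble with columns `group` and `age`.
#' @return The input with no missing ages.
#' @export
impute_age <- function(panel) {
  assert_columns(panel, c("group", "age"), "panel")
  for (g in unique(panel$group)) {
    in_g <- panel$group == g
    ages <- panel$age[in_g]
    if (all(is.na(ages))) {
      stop_input("group '%s' has no non-missing ages to impute from", g)
    }
    panel$age[in_g & is.na(panel$age)] <- mean(ages, na.rm = TRUE)
  }
  panel
}

#' Recode missing gender as "unknown"
#'
#' @param panel A tibble with a `gender` column.
#' @return The input with `gender` in `{woman, man, unknown}` and no `NA`s.
#' @export
encode_missing_gender <- function(panel) {
  assert_columns(panel, "gender", "panel")
  panel$gender[is.na(panel$gender)] <- "unknown"
  panel
}

#' Replace system-error outlier weeks with group-week means
#'
#' Weekly step totals above `threshold` (which no adult can walk; the raw
#' data contain system-error records of tens of millions of steps) are
#' replaced by the mean weekly steps of the same group in the same week,
#' computed over the non-outlying values. Idempotent, strict inequality:
#' a value exactly at the threshold is kept.
#'
#' @param panel A panel tibble with `group`, `week`, `weekly_steps`.
#' @param threshold Physical upper bound on weekly steps. The default,
#'   560,000, is 10 hours of walking a day for 7 days at average speed.
#' @return The panel with no `weekly_steps` above `threshold`.
#' @export
replace_outliers <- function(panel, threshold = 560000) {
  assert_columns(panel, c("group", "week", "weekly_steps"), "panel")
  if (length(threshold) != 1 || threshold <= 0) {
    stop_input("`threshold` must be a single positive number")
  }
  is_out <- panel$weekly_steps > threshold
  if (!any(is_out)) return(panel)
  key <- paste(panel$group, panel$week)
  for (k in unique(key[is_out])) {
    in_k <- key == k
    clean <- panel$weekly_steps[in_k & !is_out]
    if (length(clean) == 0) {
      stop_input("every value in group-week '%s' exceeds the threshold; no clean mean available", k)
    }
    panel$weekly_steps[in_k & is_out] <- mean(clean)
  }
  panel
}

#' Apply the full cleaning sequence
#'
#' Group-mean age imputation, unknown-gender coding, and outlier replacement,
#' in that order. Never changes the number of rows.
#'
#' @inheritParams replace_outliers
#' @return The cleaned panel.
#' @export
clean_panel <- function(panel, threshold = 560000) {
  replace_outliers(encode_missing_gender(impute_age(panel)), threshold)
}

#' Classify users by baseline activity
#'
#' Within each requested group, users are ranked on their total steps over
#' weeks 6 and 7 and split at the empirical 25th and 75th percentiles
#' (linear interpolation): first quartile low-active, middle two quartiles
#' medium-active, fourth quartile high-active. Values equal to a cut point
#' fall to the lower class; a fully tied group degenerates to all-medium.
#' Invariant under any strictly increasing transform of the totals.
#'
#' @param panel A cleaned panel containing weeks 6 and 7 for every user.
#' @param groups Character vector of group labels to classify (default: the
#'   two personalization groups).
#' @return A tibble with columns `user_id`, `group`, `activity_class`.
#' @export
classify_activity <- function(panel,
                              groups = c("personalized_by_you",
                                         "personalized_by_algorithm")) {
  assert_columns(panel, c("user_id", "week", "weekly_steps", "group"),
                 "panel")
  pre <- dplyr::filter(panel, .data$week %in% c(6, 7),
                       .data$group %in% groups)
  totals <- dplyr::summarise(
    dplyr::group_by(pre, .data$user_id, .data$group),
    total = sum(.data$weekly_steps), n_weeks = dplyr::n(), .groups = "drop")
  if (any(totals$n_weeks != 2)) {
    stop_input("every user must have both week 6 and week 7 present")
  }
  out <- dplyr::group_by(totals, .data$group)
  sizes <- dplyr::summarise(out, n = dplyr::n())
  if (any(sizes$n < 4)) {
    stop_input("group '%s' has fewer than 4 users; quartiles are undefined",
               sizes$group[sizes$n < 4][1])
  }
  out <- dplyr::mutate(out, activity_class = quartile_classes(.data$total))
  dplyr::select(dplyr::ungroup(out), "user_id", "group", "activity_class")
}
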