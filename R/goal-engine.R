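#' Rank of the observation just below the median
#'
#' The adaptive goal algorithm sorts a user's recent daily step counts in
#' ascending order and selects the observation just below the median as the
#' new daily goal, so that the target is usually attainable yet above a lazy
#' day. For `n` sorted observations the selected 1-based rank is
#' `ceiling(n / 2) - 1`: with 10 observations the 4th is selected, with 7 the
#' 3rd, with 28 the 13th.
#'
#' @param n Number of daily observations (a single integer, at least 3; the
#'   goal algorithm itself only calls this for `n >= 7`).
#' @return The 1-based rank (integer) into the ascending-sorted observations,
#'   strictly below the median position.
#' @examples
#' select_rank(10) # 4
#' select_rank(7)  # 3
#' select_rank(28) # 13
#' @export
select_rank <- function(n) {
  if (length(n) != 1L || !is.numeric(n) || is.na(n) || n != as.integer(n)) {
    stop_input("`n` must be a single integer")
  }
  if (n < 3) {
    stop_input(paste0("`n` must be at least 3: with ", n, " observation(s) ",
                      "no observation lies strictly below the median"))
  }
  as.integer(ceiling(n / 2) - 1)
}

#' Round a step count to the nearest hundred
#'
#' Midpoints (values ending in 50) round up.
#'
#' @param x A positive numeric vector of step counts.
#' @return `x` rounded to the nearest multiple of 100 (half-up).
#' @examples
#' round_to_hundred(4567) # 4600
#' round_to_hundred(2550) # 2600
#' @export
round_to_hundred <- function(x) {
  if (!is.numeric(x) || any(is.na(x)) || any(x <= 0)) {
    stop_input("`x` must be positive")
  }
  round_half_up(x, 100)
}

new_goal_decision <- function(daily_steps, method) {
  daily_steps <- as.integer(daily_steps)
  ok <- switch(method,
    default   = daily_steps == 2000L,
    self_set  = daily_steps >= 1000L && daily_steps <= 20000L,
    algorithm = daily_steps %% 100L == 0L &&
                daily_steps >= 2000L && daily_steps <= 8000L,
    fallback  = daily_steps %in% c(1500L, 3500L),
    stop_input("unknown goal method '%s'", method)
  )
  if (!ok) {
    stop_input("daily goal %d violates the constraints of method '%s'",
               daily_steps, method)
  }
  structure(
    list(daily_steps = daily_steps, days_per_week = 5L, method = method),
    class = "goal_decision"
  )
}

#' @export
print.goal_decision <- function(x, ...) {
  cat(sprintf("<goal_decision> %d steps/day, %d days/week [%s]\n",
              x$daily_steps, x$days_per_week, x$method))
  invisible(x)
}

#' Default step goal
#'
#' Every app user starts with a default goal of 2000 steps per day, 5 days a
#' week.
#'
#' @return A `goal_decision` with `daily_steps = 2000`, `days_per_week = 5`
#'   and `method = "default"`.
#' @export
default_goal <- function() {
  new_goal_decision(2000L, "default")
}

#' Validate a self-set ("personalized-by-you") step goal
#'
#' Users choosing their own goal must pick a value within the reference range
#' of 1000 to 20,000 steps per day.
#'
#' @param requested A single positive integer, the requested daily goal.
#' @return A `goal_decision` with `method = "self_set"` if the request is in
#'   range; otherwise an error naming the `[1000, 20000]` bounds.
#' @export
validate_self_set_goal <- function(requested) {
  if (length(requested) != 1L || !is.numeric(requested) || is.na(requested) ||
      requested != as.integer(requested) || requested <= 0) {
    stop_input("`requested` must be a single positive integer")
  }
  if (requested < 1000 || requested > 20000) {
    stop_input("self-set goal %d is outside the reference range [1000, 20000]",
               as.integer(requested))
  }
  new_goal_decision(requested, "self_set")
}

#' Adaptive ("personalized-by-the-algorithm") step goal
#'
#' Implements the moving-window percentile-rank rule. With at least 7 daily
#' observations from the 4 weeks preceding assignment, the observations are
#' sorted ascending, the one just below the median ([select_rank()]) is taken,
#' rounded to the nearest hundred and constrained to the 2000--8000 range.
#' With fewer than 7 observations a survey-based fallback applies: users who
#' found the default goal too high receive 1500 steps, those who found it too
#' low receive 3500 steps.
#'
#' @param steps Numeric vector of non-negative daily step counts recorded in
#'   the 28 days preceding assignment (only days with recorded usage are
#'   present, so `length(steps)` may be anywhere in 0..28).
#' @param survey Survey answer, `"too_high"` or `"too_low"`. Users answering
#'   `"all_right"` keep the default goal and never reach this route.
#' @return A `goal_decision` with `method = "algorithm"` or
#'   `method = "fallback"`.
#' @examples
#' algorithm_goal(rep(9000, 28), "too_low")   # capped at 8000
#' algorithm_goal(c(100, 4000, 2500), "too_high") # fallback 1500
#' @export
algorithm_goal <- function(steps, survey) {
  if (length(survey) != 1L || !survey %in% c("too_high", "too_low")) {
    if (identical(survey, "all_right")) {
      stop_input("users satisfied with the default goal ('all_right') are not offered the algorithm route")
    }
    stop_input("`survey` must be 'too_high' or 'too_low'")
  }
  if (length(steps) > 28) {
    stop_input("at most 28 daily observations (4 weeks) are used")
  }
  if (length(steps) > 0 && (!is.numeric(steps) || any(is.na(steps)) || any(steps < 0))) {
    stop_input("daily step counts must be non-negative numbers")
  }
  n <- length(steps)
  if (n < 7) {
    return(new_goal_decision(if (survey == "too_high") 1500L else 3500L,
                             "fallback"))
  }
  chosen <- sort(steps)[select_rank(n)]
  raw <- if (chosen > 0) round_to_hundred(chosen) else 0
  new_goal_decision(clamp(raw, 2000, 8000), "algorithm")
}

#' Assign goals to a batch of users
#'
#' Applies the three goal routes to a cohort: satisfied users
#' (`"all_right"`) keep the default goal; dissatisfied users with a
#' `requested_goal` take the self-set route; the rest take the algorithm
#' route based on their recorded daily history.
#'
#' @param history Tibble/data frame with columns `user_id`, `date`, `steps`
#'   (one row per recorded day; at most 28 per user).
#' @param survey Tibble/data frame with columns `user_id`, `response`
#'   (`"too_high"`, `"too_low"` or `"all_right"`) and optionally
#'   `requested_goal` (non-`NA` for users who set their own goal).
#' @return A tibble with columns `user_id`, `daily_steps`, `days_per_week`,
#'   `method`, one row per surveyed user.
#' @export
assign_goals <- function(history, survey) {
  assert_columns(survey, c("user_id", "response"), "survey")
  assert_columns(history, c("user_id", "steps"), "history")
  if (!"requested_goal" %in% names(survey)) survey$requested_goal <- NA_integer_
  steps_by_user <- split(history$steps, history$user_id)
  rows <- lapply(seq_len(nrow(survey)), function(i) {
    uid <- survey$user_id[i]
    resp <- survey$response[i]
    req <- survey$requested_goal[i]
    dec <- if (identical(resp, "all_right")) {
      default_goal()
    } else if (!is.na(req)) {
      validate_self_set_goal(req)
    } else {
      algorithm_goal(steps_by_user[[as.character(uid)]] %||% numeric(0), resp)
    }
    tibble::tibble(user_id = uid, daily_steps = dec$daily_steps,
                   days_per_week = dec$days_per_week, method = dec$method)
  })
  dplyr::bind_rows(rows)
}
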