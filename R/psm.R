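#' Specification of the propensity model and matching pool
#'
#' @param treated_group Group label of the treated users
#'   (`"personalized_by_you"`, `"personalized_by_algorithm"` or
#'   `"not_changed"`).
#' @param pool Which users form the matching pool: `"both"` (survey
#'   non-responders plus the never-emailed group, the default),
#'   `"no_response"` only, or `"group2"` only. The two restricted pools
#'   implement the robustness re-runs with distinct matching samples.
#' @param covariates Covariate names; the default is the seven matching
#'   covariates (age, gender, app usage duration, week-6/7 step totals,
#'   week-6/7 days goal achieved).
#' @return A list of class `propensity_spec`.
#' @export
propensity_spec <- function(treated_group,
                            pool = c("both", "no_response", "group2"),
                            covariates = c("age", "gender", "usage_days",
                                           "steps_week6", "steps_week7",
                                           "days_achieved_week6",
                                           "days_achieved_week7")) {
  pool <- match.arg(pool)
  if (length(covariates) == 0) stop_input("covariate list must be non-empty")
  structure(list(treated_group = treated_group, pool = pool,
                 covariates = covariates),
            class = "propensity_spec")
}

pool_groups <- function(pool) {
  switch(pool,
         both = c("no_response", "group2"),
         no_response = "no_response",
         group2 = "group2")
}

#' Estimate propensity scores by logistic regression
#'
#' Fits a maximum-likelihood binary logistic model of treatment-group
#' membership on the specification's covariates over the treated users and the chosen
#' matching pool, and returns each user's fitted probability of treatment.
#'
#' @param data User-level covariate table from [user_covariates()] (cleaning
#'   must already have been applied: no missing covariates).
#' @param spec A [propensity_spec()].
#' @return A tibble of class `propensity_scores` with columns `user_id`,
#'   `group`, `treated` (0/1) and `score` in (0, 1); the fitted model's
#'   coefficients are attached as attribute `"coefficients"`.
#' @export
fit_propensity <- function(data, spec) {
  stopifnot(inherits(spec, "propensity_spec"))
  assert_columns(data, c("user_id", "group", spec$covariates), "data")
  keep <- data$group %in% c(spec$treated_group, pool_groups(spec$pool))
  d <- data[keep, , drop = FALSE]
  if (!any(d$group == spec$treated_group)) {
    stop_input("no users in treated group '%s'", spec$treated_group)
  }
  if (all(d$group == spec$treated_group)) {
    stop_input("matching pool '%s' is empty", spec$pool)
  }
  cov_d <- d[spec$covariates]
  if (anyNA(cov_d)) {
    stop_input("covariates contain missing values; run the cleaning stage first")
  }
  d$..treated <- as.integer(d$group == spec$treated_group)
  form <- stats::as.formula(paste("..treated ~",
                                  paste(spec$covariates, collapse = " + ")))
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(form, family = stats::binomial(), data = d,
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  std_coef <- abs(stats::coef(fit)[-1] *
                    apply(stats::model.matrix(fit)[, -1, drop = FALSE], 2,
                          stats::sd))
  # extreme fitted values alone are expected under heavy-tailed covariates;
  # actual (quasi-)separation shows up as a diverging coefficient or outright
  # non-convergence
  diverged <- any(!is.na(std_coef) & std_coef > 10)
  if (!fit$converged || (separated && diverged)) {
    worst <- names(which.max(std_coef))
    stop_input(paste0("propensity model did not yield interior probabilities",
                      " (possible complete separation); largest standardized",
                      " coefficient: %s"), worst)
  }
  qr_rank <- fit$qr$rank
  if (qr_rank < length(stats::coef(fit))) {
    stop_input("singular design: %s is collinear",
               paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                     collapse = ", "))
  }
  out <- tibble::tibble(user_id = d$user_id, group = d$group,
                        treated = d$..treated,
                        score = as.numeric(stats::fitted(fit)))
  attr(out, "coefficients") <- stats::coef(fit)
  attr(out, "spec") <- spec
  class(out) <- c("propensity_scores", class(out))
  out
}

#' Greedy 1:1 nearest-neighbour matching without replacement
#'
#' Treated users are processed in descending propensity-score order (ties by
#' smaller user id); each receives the still-unused pool member with the
#' smallest absolute score difference, ties again broken by smaller user id.
#' Every treated user is matched (no caliper unless set), and every control
#' is used at most once.
#'
#' @param scores A `propensity_scores` tibble from [fit_propensity()], or any
#'   tibble with columns `user_id`, `treated`, `score`.
#' @param caliper Optional maximum |score difference|; `NULL` (default)
#'   disables it. With a caliper, treated users with no candidate in range
#'   are left unmatched.
#' @return A list of class `match_result`: `pairs` (tibble `treated_id`,
#'   `control_id`, `score_treated`, `score_control`, `distance`),
#'   `unmatched_pool` (unused pool ids), `unmatched_treated` (non-empty only
#'   with a caliper).
#' @export
match_nearest_neighbor <- function(scores, caliper = NULL) {
  assert_columns(scores, c("user_id", "treated", "score"), "scores")
  tr <- scores[scores$treated == 1, ]
  po <- scores[scores$treated == 0, ]
  if (nrow(po) < nrow(tr)) {
    stop_input("pool (%d) is smaller than the treated group (%d)",
               nrow(po), nrow(tr))
  }
  tr <- tr[order(-tr$score, tr$user_id), ]
  po <- po[order(po$user_id), ]
  avail <- rep(TRUE, nrow(po))
  ctrl_idx <- integer(nrow(tr))
  matched <- rep(TRUE, nrow(tr))
  for (i in seq_len(nrow(tr))) {
    d <- abs(po$score - tr$score[i])
    d[!avail] <- Inf
    m <- min(d)
    if (!is.null(caliper) && m > caliper) {
      matched[i] <- FALSE
      next
    }
    j <- which(d == m)[1] # po sorted by user_id, so the first tie is smallest
    ctrl_idx[i] <- j
    avail[j] <- FALSE
  }
  pairs <- tibble::tibble(
    treated_id = tr$user_id[matched],
    control_id = po$user_id[ctrl_idx[matched]],
    score_treated = tr$score[matched],
    score_control = po$score[ctrl_idx[matched]]
  )
  pairs$distance <- abs(pairs$score_treated - pairs$score_control)
  structure(list(pairs = pairs,
                 unmatched_pool = po$user_id[avail],
                 unmatched_treated = tr$user_id[!matched]),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %d pairs, %d unused pool members",
              nrow(x$pairs), length(x$unmatched_pool)))
  if (length(x$unmatched_treated) > 0) {
    cat(sprintf(", %d treated unmatched (caliper)",
                length(x$unmatched_treated)))
  }
  cat(sprintf("\n  mean |score distance|: %.4g\n", mean(x$pairs$distance)))
  invisible(x)
}

#' Standardized mean difference between two samples
#'
#' Balance metric: the treated-minus-comparison mean difference divided by a
#' standard deviation, making it scale-free. The default denominator is the
#' treated-group sample SD, the convention under which the reported balance
#' tables of the study this package models are reproduced exactly; the
#' symmetric pooled form `sqrt((s_t^2 + s_c^2)/2)` is available as an option.
#' For a categorical level, pass 0/1 indicators.
#'
#' @param x_treated,x_comparison Numeric vectors (non-empty).
#' @param denominator `"treated"` (default) or `"pooled"`.
#' @return A signed number; 0 when the denominator is 0 and the means are
#'   equal; `Inf`/`-Inf` (with a warning) when the denominator is 0 but the
#'   means differ.
#' @examples
#' standardized_mean_difference(c(1, 2, 3), c(2, 3, 4))
#' @export
standardized_mean_difference <- function(x_treated, x_comparison,
                                         denominator = c("treated", "pooled")) {
  denominator <- match.arg(denominator)
  if (length(x_treated) == 0 || length(x_comparison) == 0) {
    stop_input("both samples must be non-empty")
  }
  diff <- mean(x_treated) - mean(x_comparison)
  s_t <- stats::sd(x_treated)
  s_c <- stats::sd(x_comparison)
  denom <- if (denominator == "treated") s_t else sqrt((s_t^2 + s_c^2) / 2)
  if (is.na(denom) || denom == 0) {
    if (isTRUE(all.equal(diff, 0)) || diff == 0) return(0)
    warning("degenerate SMD: zero variance with unequal means",
            call. = FALSE)
    return(sign(diff) * Inf)
  }
  diff / denom
}

#' Covariate balance before and after matching
#'
#' Summarises every matching covariate (categorical covariates per level, as
#' 0/1 indicators) in the treated group, the full matching pool and the
#' matched control group, with standardized mean differences before
#' (treated vs pool) and after (treated vs matched controls) matching.
#'
#' @param data User-level covariate table from [user_covariates()].
#' @param match A [match_nearest_neighbor()] result.
#' @param spec The [propensity_spec()] used for matching.
#' @param denominator Passed to [standardized_mean_difference()].
#' @return A tibble of class `balance_table`, one row per covariate (level)
#'   with means, SDs and pre/post SMDs.
#' @export
balance_report <- function(data, match, spec,
                           denominator = c("treated", "pooled")) {
  stopifnot(inherits(match, "match_result"), inherits(spec, "propensity_spec"))
  denominator <- match.arg(denominator)
  if (length(spec$covariates) == 0) stop_input("covariate list must be non-empty")
  assert_columns(data, c("user_id", "group", spec$covariates), "data")
  treated <- data[data$group == spec$treated_group, ]
  pool <- data[data$group %in% pool_groups(spec$pool), ]
  ctrl <- data[base::match(match$pairs$control_id, data$user_id), ]

  expand <- function(d) {
    cols <- list()
    for (v in spec$covariates) {
      x <- d[[v]]
      if (is.numeric(x)) {
        cols[[v]] <- x
      } else {
        for (lev in sort(unique(data[[v]]))) {
          cols[[paste0(v, "_", lev)]] <- as.numeric(x == lev)
        }
      }
    }
    cols
  }
  t_cols <- expand(treated); p_cols <- expand(pool); c_cols <- expand(ctrl)
  rows <- lapply(names(t_cols), function(v) {
    tibble::tibble(
      covariate = v,
      mean_treated = mean(t_cols[[v]]), sd_treated = stats::sd(t_cols[[v]]),
      mean_pool = mean(p_cols[[v]]), sd_pool = stats::sd(p_cols[[v]]),
      smd_pre = standardized_mean_difference(t_cols[[v]], p_cols[[v]],
                                             denominator),
      mean_matched = mean(c_cols[[v]]), sd_matched = stats::sd(c_cols[[v]]),
      smd_post = standardized_mean_difference(t_cols[[v]], c_cols[[v]],
                                              denominator)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("balance_table", class(out))
  out
}
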