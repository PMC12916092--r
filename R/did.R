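#' Assemble the matched estimation panel for one comparison
#'
#' Restricts a user-week panel to one treated group and its matched controls.
#' Controls never personalize, so their treatment indicator is 0 throughout;
#' treated users carry 1 from week 8 on.
#'
#' @param panel A cleaned panel tibble.
#' @param match A [match_nearest_neighbor()] result.
#' @return The panel subset, with a `pair_id` column (controls share their
#'   treated partner's pair id) and a `treated` 0/1 column.
#' @export
build_did_panel <- function(panel, match) {
  stopifnot(inherits(match, "match_result"))
  assert_columns(panel, c("user_id", "week", "weekly_steps",
                          "personalization"), "panel")
  pairs <- match$pairs
  map <- tibble::tibble(
    user_id = c(pairs$treated_id, pairs$control_id),
    pair_id = rep(seq_len(nrow(pairs)), 2),
    treated = rep(c(1L, 0L), each = nrow(pairs))
  )
  dplyr::inner_join(panel, map, by = "user_id")
}

check_balanced <- function(panel) {
  counts <- table(panel$user_id)
  if (length(unique(panel$week)) * length(counts) != nrow(panel) ||
      any(counts != length(unique(panel$week)))) {
    stop_input(paste0("panel is unbalanced: every user must contribute the ",
                      "same weeks; balance the panel or estimate with ",
                      "explicit individual/week dummies"))
  }
  invisible(panel)
}

#' Two-way within transformation
#'
#' Removes individual and week fixed effects from the outcome and the
#' treatment indicator by double demeaning on a balanced panel:
#' `v_it - mean_i(v) - mean_t(v) + mean(v)`. The transformed columns are
#' orthogonal to both sets of indicator variables, so the slope of the
#' transformed regression equals the two-way fixed-effects estimate.
#'
#' @param panel A balanced panel tibble.
#' @param outcome,treatment Column names (defaults `weekly_steps`,
#'   `personalization`).
#' @return A tibble `user_id`, `week`, `y_within`, `x_within`.
#' @export
within_transform <- function(panel, outcome = "weekly_steps",
                             treatment = "personalization") {
  assert_columns(panel, c("user_id", "week", outcome, treatment), "panel")
  check_balanced(panel)
  id <- factor(panel$user_id)
  wk <- factor(panel$week)
  demean2 <- function(v) {
    v - stats::ave(v, id) - stats::ave(v, wk) + mean(v)
  }
  tibble::tibble(user_id = panel$user_id, week = panel$week,
                 y_within = demean2(as.numeric(panel[[outcome]])),
                 x_within = demean2(as.numeric(panel[[treatment]])))
}

#' Robust standard error of a within-regression slope
#'
#' Sandwich standard error for the slope of a single demeaned regressor,
#' with a degrees-of-freedom correction that counts the absorbed fixed
#' effects among the model parameters. `"hc1"` gives the
#' heteroskedasticity-robust form; `"cluster"` the cluster-robust (CR1) form
#' with scores summed within clusters.
#'
#' @param x Demeaned regressor.
#' @param residuals Regression residuals.
#' @param n_params Total number of model parameters, including the absorbed
#'   individual and week effects and the slope.
#' @param type `"hc1"` or `"cluster"`.
#' @param cluster Cluster membership (required for `type = "cluster"`).
#' @return The standard error (a single number).
#' @export
robust_se <- function(x, residuals, n_params, type = c("hc1", "cluster"),
                      cluster = NULL) {
  type <- match.arg(type)
  n <- length(x)
  if (n <= n_params) {
    stop_input("fewer observations (%d) than model parameters (%d)",
               n, n_params)
  }
  sxx <- sum(x^2)
  if (type == "hc1") {
    v <- n / (n - n_params) * sum(x^2 * residuals^2) / sxx^2
  } else {
    if (is.null(cluster)) stop_input("cluster membership required")
    h <- rowsum(x * residuals, cluster)
    g <- nrow(h)
    v <- g / (g - 1) * (n - 1) / (n - n_params) * sum(h^2) / sxx^2
  }
  sqrt(v)
}

#' Two-way fixed-effects difference-in-differences estimate
#'
#' Estimates the weekly-step effect of goal personalization from the model
#' `steps_it = b0 + b1 * personalization_it + theta_i + lambda_t + eps_it`
#' by the within estimator: both sides are double-demeaned and `b1` is the
#' OLS slope of the transformed outcome on the transformed treatment
#' indicator, numerically identical to OLS with explicit individual and week
#' dummies. The intercept is absorbed by the fixed effects and not reported.
#'
#' @param panel A balanced estimation panel (see [build_did_panel()]) with
#'   columns `user_id`, `week`, `weekly_steps`, `personalization`.
#' @param se `"hc1"` (heteroskedasticity-robust, default) or `"cluster"`
#'   (cluster-robust by individual).
#' @return An object of class `did_estimate`: `beta1`, `se`, `t_stat`,
#'   `p_value`, `n_obs`, `n_individuals`, `se_type`, `df`.
#' @export
estimate_did <- function(panel, se = c("hc1", "cluster")) {
  se <- match.arg(se)
  tw <- within_transform(panel)
  if (max(abs(tw$x_within)) < 1e-12) {
    stop_input(paste0("treatment indicator has no variation after removing ",
                      "individual and week effects; the panel must mix ",
                      "treated and control users over pre and post weeks"))
  }
  sxx <- sum(tw$x_within^2)
  beta1 <- sum(tw$x_within * tw$y_within) / sxx
  resid <- tw$y_within - beta1 * tw$x_within
  n_ind <- length(unique(tw$user_id))
  n_wk <- length(unique(tw$week))
  n_params <- n_ind + (n_wk - 1) + 1
  se_val <- robust_se(tw$x_within, resid, n_params, type = se,
                      cluster = if (se == "cluster") tw$user_id)
  df <- if (se == "cluster") n_ind - 1 else nrow(tw) - n_params
  t_stat <- beta1 / se_val
  structure(list(
    beta1 = beta1, se = se_val, t_stat = t_stat,
    p_value = 2 * stats::pt(-abs(t_stat), df),
    n_obs = nrow(tw), n_individuals = n_ind,
    se_type = se, df = df
  ), class = "did_estimate")
}

#' @export
print.did_estimate <- function(x, ...) {
  cat("<did_estimate> two-way fixed-effects within estimator\n")
  cat(sprintf("  personalization effect: %.3f weekly steps (%s SE %.3f)\n",
              x$beta1, toupper(x$se_type), x$se))
  cat(sprintf("  t = %.3f, p = %.4g, observations = %d, individuals = %d\n",
              x$t_stat, x$p_value, x$n_obs, x$n_individuals))
  invisible(x)
}

#' Event-study decomposition of the personalization effect
#'
#' Replaces the single treatment term with treated-group-by-week
#' interactions, week 7 (the last pre-treatment week) as the reference, all
#' fixed effects retained. The week-6 coefficient probes the parallel-trends
#' assumption: under a common trend it should be indistinguishable from
#' zero; the week-8..11 coefficients trace the dynamic effect.
#'
#' @inheritParams estimate_did
#' @param ref_week Reference week (default 7).
#' @return An object of class `event_study_result`: a tibble with one row
#'   per non-reference week (`week`, `estimate`, `se`, `t_stat`, `p_value`),
#'   the reference week's coefficient being fixed at 0 by construction.
#' @export
event_study <- function(panel, se = c("hc1", "cluster"), ref_week = 7) {
  se <- match.arg(se)
  assert_columns(panel, c("user_id", "week", "weekly_steps",
                          "personalization"), "panel")
  check_balanced(panel)
  treated_i <- stats::ave(panel$personalization, panel$user_id,
                          FUN = max)
  if (max(treated_i) == 0) {
    stop_input("no treated users in the panel")
  }
  weeks <- sort(unique(panel$week))
  if (!ref_week %in% weeks) stop_input("reference week %s absent", ref_week)
  ev_weeks <- setdiff(weeks, ref_week)
  id <- factor(panel$user_id)
  wk <- factor(panel$week)
  demean2 <- function(v) v - stats::ave(v, id) - stats::ave(v, wk) + mean(v)
  X <- vapply(ev_weeks,
              function(w) demean2(as.numeric(treated_i * (panel$week == w))),
              numeric(nrow(panel)))
  y <- demean2(as.numeric(panel$weekly_steps))
  xtx <- crossprod(X)
  if (rcond(xtx) < 1e-12) {
    stop_input("interaction design is singular after demeaning")
  }
  beta <- drop(solve(xtx, crossprod(X, y)))
  resid <- y - drop(X %*% beta)
  n <- nrow(panel)
  n_ind <- length(unique(panel$user_id))
  n_params <- n_ind + (length(weeks) - 1) + length(ev_weeks)
  if (n <= n_params) stop_input("fewer observations than model parameters")
  bread <- solve(xtx)
  if (se == "hc1") {
    meat <- crossprod(X, X * resid^2)
    V <- n / (n - n_params) * bread %*% meat %*% bread
    df <- n - n_params
  } else {
    scores <- rowsum(X * resid, panel$user_id)
    g <- nrow(scores)
    meat <- crossprod(scores)
    V <- g / (g - 1) * (n - 1) / (n - n_params) * bread %*% meat %*% bread
    df <- g - 1
  }
  ses <- sqrt(diag(V))
  t_stat <- beta / ses
  out <- tibble::tibble(week = ev_weeks, estimate = beta, se = ses,
                        t_stat = t_stat,
                        p_value = 2 * stats::pt(-abs(t_stat), df))
  attr(out, "ref_week") <- ref_week
  attr(out, "se_type") <- se
  class(out) <- c("event_study_result", class(out))
  out
}

#' Compare two independent difference-in-differences estimates
#'
#' Normal-approximation test of the equality of two effects estimated on
#' independent (separately matched) samples:
#' `t = (b_a - b_b) / sqrt(se_a^2 + se_b^2)`, two-sided p-value.
#'
#' @param est_a,est_b Two [estimate_did()] results (or lists with `beta1`
#'   and `se`).
#' @return A list with `t_stat`, `p_value`, and the effect difference.
#' @export
compare_effects <- function(est_a, est_b) {
  if (est_a$se <= 0 || est_b$se <= 0) {
    stop_input("standard errors must be positive")
  }
  diff <- est_a$beta1 - est_b$beta1
  t_stat <- diff / sqrt(est_a$se^2 + est_b$se^2)
  list(difference = diff, t_stat = t_stat,
       p_value = 2 * stats::pnorm(-abs(t_stat)))
}
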