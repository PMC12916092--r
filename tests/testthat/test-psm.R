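fixture_20 <- function() {
  # deterministic 20-row, 2-covariate fixture
  set.seed(7)
  x1 <- round(stats::rnorm(20, 0, 1), 3)
  x2 <- round(stats::runif(20, -1, 1), 3)
  eta <- 0.4 + 0.9 * x1 - 1.2 * x2
  y <- as.integer(stats::runif(20) < stats::plogis(eta))
  tibble::tibble(user_id = 1:20, group = ifelse(y == 1, "t", "no_response"),
                 x1 = x1, x2 = x2)
}

test_that("propensity coefficients match an independent Newton/IRLS oracle", {
  d <- fixture_20()
  spec <- propensity_spec("t", pool = "no_response",
                          covariates = c("x1", "x2"))
  scores <- fit_propensity(d, spec)
  beta_pkg <- unname(attr(scores, "coefficients"))
  beta_oracle <- unname(oracle_logit(d[, c("x1", "x2")],
                                     as.integer(d$group == "t")))
  expect_equal(beta_pkg, beta_oracle, tolerance = 1e-6)
  # maximum likelihood: the score equations are solved to high precision
  X1 <- cbind(1, d$x1, d$x2)
  resid <- as.integer(d$group == "t") - scores$score[order(scores$user_id)]
  expect_lt(max(abs(crossprod(X1, resid))), 1e-6)
  expect_true(all(scores$score > 0 & scores$score < 1))
})

test_that("no-signal treatment yields uninformative scores (AUC about 0.5)", {
  set.seed(77)
  n <- 2000
  d <- tibble::tibble(
    user_id = seq_len(n),
    group = sample(c("t", "no_response"), n, replace = TRUE,
                   prob = c(0.3, 0.7)),
    x1 = stats::rnorm(n), x2 = stats::rnorm(n)
  )
  scores <- fit_propensity(d, propensity_spec("t", pool = "no_response",
                                              covariates = c("x1", "x2")))
  r <- rank(scores$score)
  n1 <- sum(scores$treated); n0 <- sum(1 - scores$treated)
  auc <- (sum(r[scores$treated == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  expect_lt(abs(auc - 0.5), 0.03)
  expect_lt(abs(mean(scores$score) - n1 / n), 0.02)
})

test_that("selection on baseline steps pushes treated scores above the pool", {
  cohort <- simulate_cohort(scaled_config(seed = 101))
  covars <- user_covariates(clean_panel(cohort$panel))
  scores <- fit_propensity(covars, propensity_spec("personalized_by_you"))
  expect_gt(mean(scores$score[scores$treated == 1]),
            mean(scores$score[scores$treated == 0]))
})

test_that("perfect separation and singular designs are flagged", {
  d <- tibble::tibble(user_id = 1:10,
                      group = rep(c("t", "no_response"), each = 5),
                      x1 = c(1:5, 11:15))
  expect_error(
    fit_propensity(d, propensity_spec("t", "no_response", covariates = "x1")),
    "separation")
  d2 <- tibble::tibble(user_id = 1:20, group = fixture_20()$group,
                       x1 = fixture_20()$x1, x2 = 2 * fixture_20()$x1)
  expect_error(
    fit_propensity(d2, propensity_spec("t", "no_response",
                                       covariates = c("x1", "x2"))),
    "collinear|singular")
})

test_that("greedy nearest-neighbour matching follows the documented contract", {
  scores <- tibble::tibble(
    user_id = c(1, 2, 11, 12, 13),
    treated = c(1, 1, 0, 0, 0),
    score = c(0.9, 0.5, 0.85, 0.55, 0.1)
  )
  m <- match_nearest_neighbor(scores)
  expect_equal(m$pairs$treated_id, c(1, 2))
  expect_equal(m$pairs$control_id, c(11, 12))
  expect_equal(m$unmatched_pool, 13)

  # pool duplicating the treated scores matches at distance zero
  dup <- tibble::tibble(user_id = 1:6, treated = rep(c(1, 0), each = 3),
                        score = rep(c(0.2, 0.5, 0.8), 2))
  expect_equal(match_nearest_neighbor(dup)$pairs$distance, rep(0, 3))

  # one treated picks the closer of two candidates
  one <- tibble::tibble(user_id = 1:3, treated = c(1, 0, 0),
                        score = c(0.2, 0.2, 0.21))
  expect_equal(match_nearest_neighbor(one)$pairs$control_id, 2)

  # equidistant candidates resolve to the smaller user id
  tie <- tibble::tibble(user_id = c(1, 5, 3), treated = c(1, 0, 0),
                        score = c(0.5, 0.25, 0.75))
  expect_equal(match_nearest_neighbor(tie)$pairs$control_id, 3)

  small_pool <- tibble::tibble(user_id = 1:3, treated = c(1, 1, 0),
                               score = c(0.1, 0.2, 0.3))
  expect_error(match_nearest_neighbor(small_pool), "smaller than")
})

test_that("matching is without replacement and every treated user is matched", {
  cohort <- simulate_cohort(scaled_config(seed = 111))
  covars <- user_covariates(clean_panel(cohort$panel))
  scores <- fit_propensity(covars, propensity_spec("not_changed"))
  m <- match_nearest_neighbor(scores)
  expect_equal(nrow(m$pairs), sum(scores$treated))
  expect_equal(max(table(m$pairs$control_id)), 1)
  expect_equal(length(m$unmatched_treated), 0)
  # a tight caliper leaves some treated unmatched instead of stretching
  mc <- match_nearest_neighbor(scores, caliper = 1e-6)
  expect_lt(nrow(mc$pairs), nrow(m$pairs))
  expect_true(all(mc$pairs$distance <= 1e-6))
})

test_that("greedy matching is compared against the brute-force optimum", {
  # exhaustive assignment oracle on small instances
  brute_optimal <- function(tr, po) {
    combos <- utils::combn(length(po), length(tr), simplify = FALSE)
    best <- Inf
    for (cb in combos) {
      for (perm in combinat_perms(cb)) {
        best <- min(best, sum(abs(tr - po[perm])))
      }
    }
    best
  }
  combinat_perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in combinat_perms(v[-i])) out <- c(out, list(c(v[i], rest)))
    }
    out
  }
  set.seed(123)
  subopt <- 0
  for (i in 1:12) {
    n_t <- sample(2:4, 1); n_p <- n_t + sample(1:3, 1)
    tr <- round(stats::runif(n_t), 3)
    po <- round(stats::runif(n_p), 3)
    scores <- tibble::tibble(
      user_id = seq_len(n_t + n_p),
      treated = rep(c(1, 0), c(n_t, n_p)),
      score = c(tr, po)
    )
    greedy_total <- sum(match_nearest_neighbor(scores)$pairs$distance)
    opt <- brute_optimal(tr, po)
    expect_gte(greedy_total, opt - 1e-12)
    if (greedy_total > opt + 1e-12) subopt <- subopt + 1
  }
  # greedy is the contract, not optimality; it may (and occasionally does)
  # exceed the optimal total distance
  expect_lte(subopt, 12)
})

test_that("standardized mean differences reproduce the published balance rows", {
  # week-6 steps, age and gender rows of the personalized-by-you balance
  # table, from the printed group summaries (treated-SD denominator)
  smd_summary <- function(m_t, m_c, sd_t) (m_t - m_c) / sd_t
  expect_equal(smd_summary(48527.896, 14648.264, 26162.616), 1.295,
               tolerance = 1e-3)
  expect_equal(smd_summary(52.7, 54.786, 10.945), -0.191, tolerance = 1e-2)

  set.seed(9)
  x <- stats::rnorm(200, 5, 2); y <- stats::rnorm(300, 4, 3)
  expect_equal(standardized_mean_difference(x, x), 0)
  expect_equal(standardized_mean_difference(3 * x, 3 * y),
               standardized_mean_difference(x, y), tolerance = 1e-12)
  expect_equal(
    standardized_mean_difference(x, y, "pooled"),
    (mean(x) - mean(y)) / sqrt((var(x) + var(y)) / 2), tolerance = 1e-12)
  expect_equal(standardized_mean_difference(rep(1, 5), rep(1, 7)), 0)
  expect_warning(
    inf_smd <- standardized_mean_difference(rep(1, 5), rep(2, 7)),
    "degenerate")
  expect_identical(inf_smd, -Inf)
  expect_error(standardized_mean_difference(numeric(0), 1:3), "non-empty")
})

test_that("balance report covers every covariate level and detects perfect matches", {
  cohort <- simulate_cohort(scaled_config(seed = 121))
  covars <- user_covariates(clean_panel(cohort$panel))
  spec <- propensity_spec("personalized_by_you")
  scores <- fit_propensity(covars, spec)
  m <- match_nearest_neighbor(scores)
  bal <- balance_report(covars, m, spec)
  expect_true(all(c("age", "gender_woman", "gender_man", "steps_week6") %in%
                    bal$covariate))
  expect_false(anyNA(bal$smd_pre))

  # pool made of clones of the treated users balances exactly
  treated <- covars[covars$group == "personalized_by_you", ]
  clones <- treated
  clones$user_id <- clones$user_id + 10000
  clones$group <- "no_response"
  clone_data <- dplyr::bind_rows(treated, clones)
  n_tr <- nrow(treated)
  clone_scores <- tibble::tibble(user_id = clone_data$user_id,
                                 treated = rep(c(1, 0), each = n_tr),
                                 score = rep(seq_len(n_tr), 2) / 1000)
  cm <- match_nearest_neighbor(clone_scores)
  cb <- balance_report(clone_data, cm, propensity_spec("personalized_by_you",
                                                       pool = "no_response"))
  expect_true(all(abs(cb$smd_post) < 1e-12))
  expect_error(propensity_spec("t", covariates = character(0)), "non-empty")
})
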