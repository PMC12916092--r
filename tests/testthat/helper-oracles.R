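# Independent oracles and shared fixtures for the test suite.

# Hand-written Newton/IRLS maximum-likelihood logistic regression,
# independent of stats::glm. X excludes the intercept column.
oracle_logit <- function(X, y, tol = 1e-10, maxit = 100) {
  X1 <- cbind(1, as.matrix(X))
  beta <- rep(0, ncol(X1))
  for (i in seq_len(maxit)) {
    eta <- drop(X1 %*% beta)
    p <- 1 / (1 + exp(-eta))
    W <- p * (1 - p)
    score <- crossprod(X1, y - p)
    H <- crossprod(X1, X1 * W)
    step <- solve(H, score)
    beta <- beta + step
    if (max(abs(score)) < tol) break
  }
  drop(beta)
}

# Dummy-variable OLS estimate of the two-way fixed-effects slope.
oracle_did_lm <- function(panel) {
  fit <- stats::lm(weekly_steps ~ personalization + factor(user_id) +
                     factor(week), data = panel)
  unname(stats::coef(fit)["personalization"])
}

# Build a balanced panel tibble from per-user parameters.
make_panel <- function(theta, treated, weeks = 6:11, lambda = rep(0, length(weeks)),
                       effect = 0, noise = NULL, post_from = 8) {
  n <- length(theta)
  if (is.null(noise)) noise <- matrix(0, n, length(weeks))
  rows <- lapply(seq_along(weeks), function(j) {
    w <- weeks[j]
    post <- as.integer(w >= post_from & treated == 1)
    tibble::tibble(
      user_id = seq_len(n), week = w,
      weekly_steps = theta + lambda[j] + effect * post + noise[, j],
      personalization = post
    )
  })
  dplyr::bind_rows(rows)
}

# Random small panel for oracle-equivalence checks.
random_panel <- function(n_users = 8, seed = 1) {
  set.seed(seed)
  theta <- stats::rnorm(n_users, 100, 30)
  treated <- as.integer(seq_len(n_users) <= n_users / 2)
  lambda <- stats::rnorm(6, 0, 5)
  noise <- matrix(stats::rnorm(n_users * 6, 0, 10), n_users, 6)
  make_panel(theta, treated, lambda = lambda,
             effect = stats::runif(1, -20, 20), noise = noise)
}

# Scaled-down study cohort used by the Monte-Carlo suites (about a quarter
# of the deployment's group sizes; anomaly injection switched off where a
# run isolates estimator behaviour).
scaled_config <- function(seed, ..., anomalies = TRUE) {
  simulation_config(
    n_users = 1450,
    group_sizes = c(personalized_by_you = 58, personalized_by_algorithm = 59,
                    not_changed = 233, group2 = 500),
    missing_age_frac = if (anomalies) 0.05 else 0,
    missing_gender_frac = if (anomalies) 0.03 else 0,
    outlier_frac = if (anomalies) 0.001 else 0,
    seed = seed,
    ...
  )
}

# One matched DID estimate for a treated group of a simulated cohort.
match_and_estimate <- function(panel, covars, group, se = "hc1",
                               pool = "both") {
  spec <- propensity_spec(group, pool = pool)
  scores <- fit_propensity(covars, spec)
  m <- match_nearest_neighbor(scores)
  list(match = m,
       estimate = estimate_did(build_did_panel(panel, m), se = se))
}
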