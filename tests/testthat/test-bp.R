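d_tiny <- two_sample(cases = c(1.5, 3), controls = c(1, 2))

test_that("BP fit builds survival coefficients over unique control order statistics", {
  fit <- bp_fit(d_tiny)
  expect_s3_class(fit, "bernstein_roc_fit")
  expect_equal(fit$degree, 2L)
  expect_equal(fit$coefficients, c(1, 1, 0.5))
  expect_equal(fit$bandwidth_rule, "BP")

  # tied controls collapse to a single unique value
  d_tied <- two_sample(cases = c(0.5, 2), controls = c(1, 1, 1))
  fit_tied <- bp_fit(d_tied)
  expect_equal(fit_tied$degree, 1L)
  expect_equal(fit_tied$coefficients, c(1, 0.5))

  # leading coefficient is always 1 (survival at -Inf)
  set.seed(11)
  for (i in 1:10) {
    f <- bp_fit(random_two_sample())
    expect_equal(f$coefficients[1], 1)
    expect_true(all(diff(f$coefficients) <= 0))
    expect_true(all(f$coefficients >= 0 & f$coefficients <= 1))
  }
})

test_that("BP evaluation honours the endpoint and interior contracts", {
  fit <- bp_fit(d_tiny)
  expect_identical(bp_evaluate(fit, 1), 1)
  expect_equal(bp_evaluate(fit, 0), 0.5)  # 1 - F1_hat(max control)
  expect_equal(bp_evaluate(fit, 0.5), 0.875)
  expect_error(bp_evaluate(fit, 1.2), "\\[0, 1\\]")

  # u = 1 is exact (not merely close) and u = 0 equals the case survival
  # at the largest control, for arbitrary data
  set.seed(23)
  for (i in 1:10) {
    d <- random_two_sample()
    f <- bp_fit(d)
    expect_identical(bp_evaluate(f, 1), 1)
    expect_equal(bp_evaluate(f, 0),
                 1 - empirical_cdf(d$cases, max(d$controls)))
  }
})

test_that("explicit-degree smoothing uses empirical ROC node values", {
  f1 <- bp_general(d_tiny, 1)
  expect_equal(bp_evaluate(f1, 0.5), 0.75)
  # degree-1 fit is the straight line between R(0) and R(1)
  u <- seq(0, 1, by = 0.1)
  r0 <- empirical_roc(d_tiny, 0)
  r1 <- empirical_roc(d_tiny, 1)
  expect_equal(bp_evaluate(f1, u), (1 - u) * r0 + u * r1)
  expect_error(bp_general(d_tiny, 0), ">= 1")
})

test_that("step counting includes both endpoints of the staircase", {
  expect_equal(count_eroc_steps(d_tiny), 3L)
  # a single case above every control: levels collapse to {1}, plus the
  # missing 0 level
  d_one <- two_sample(cases = 10, controls = c(1, 2, 3))
  expect_equal(count_eroc_steps(d_one), 2L)
  set.seed(31)
  for (i in 1:15) {
    d <- random_two_sample()
    m <- count_eroc_steps(d)
    expect_gte(m, 2L)
    expect_lte(m, length(unique(d$controls)) + 2L)
  }
})

test_that("BPa composes the step count with explicit-degree smoothing", {
  fit <- bpa_fit(d_tiny)
  expect_equal(fit$degree, 3L)
  expect_equal(fit$bandwidth_rule, "BPa")
  expect_equal(fit$coefficients, empirical_roc(d_tiny, (0:3) / 3))
  expect_equal(fit$coefficients, c(0.5, 0.5, 1, 1))
  expect_identical(bp_evaluate(fit, 1), 1)
  # convex combination: bounded by the node value range
  u <- seq(0, 1, by = 0.05)
  vals <- bp_evaluate(fit, u)
  expect_true(all(vals >= min(fit$coefficients) - 1e-12))
  expect_true(all(vals <= max(fit$coefficients) + 1e-12))
})

test_that("Bernstein ROC estimates are non-decreasing in u", {
  set.seed(47)
  u <- seq(0, 1, by = 0.01)
  for (i in 1:10) {
    d <- random_two_sample()
    expect_nondecreasing(bp_evaluate(bp_fit(d), u))
    expect_nondecreasing(bp_evaluate(bpa_fit(d), u))
  }
})

test_that("large explicit degrees converge to the empirical staircase away from jumps", {
  set.seed(59)
  d <- two_sample(cases = rnorm(10, 1), controls = rnorm(10))
  n0 <- length(d$controls)
  grid <- seq(0.01, 0.99, by = 0.01)
  # keep only grid points bounded away from the staircase jump locations
  # k / n0, where the target step function is discontinuous
  away <- grid[vapply(grid, function(u) {
    min(abs(u - (0:n0) / n0)) > 0.04
  }, logical(1))]
  eroc <- empirical_roc(d, away)
  err <- function(m) max(abs(bp_evaluate(bp_general(d, m), away) - eroc))
  e_small <- err(10 * (length(d$cases) + n0))
  e_large <- err(40 * (length(d$cases) + n0))
  expect_lt(e_large, e_small)
  expect_lt(e_large, 0.05)
})

test_that("rank-based estimators are invariant under strictly increasing transformations", {
  set.seed(73)
  u <- seq(0, 1, by = 0.02)
  transforms <- list(exp, function(x) x^3, function(x) 5 * x - 2)
  for (i in 1:5) {
    d <- random_two_sample()
    for (tr in transforms) {
      d_tr <- two_sample(tr(d$cases), tr(d$controls))
      expect_equal(empirical_roc(d_tr, u), empirical_roc(d, u))
      expect_equal(bp_evaluate(bp_fit(d_tr), u),
                   bp_evaluate(bp_fit(d), u))
      expect_equal(bp_evaluate(bpa_fit(d_tr), u),
                   bp_evaluate(bpa_fit(d), u))
    }
  }
})
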