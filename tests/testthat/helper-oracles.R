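# Brute-force staircase oracle: for every u, pick the control order
# statistic with index floor(n0 * (1 - u)) + 1 (clamped to n0) and count
# the fraction of cases strictly above it.  Kept deliberately independent
# of the package's empirical_cdf/empirical_quantile composition.
oracle_empirical_roc <- function(cases, controls, u) {
  n0 <- length(controls)
  sorted0 <- sort(controls)
  vapply(u, function(ui) {
    idx <- min(floor(n0 * (1 - ui)) + 1, n0)
    threshold <- sorted0[idx]
    sum(cases > threshold) / length(cases)
  }, numeric(1))
}

random_two_sample <- function(n1 = NULL, n0 = NULL, max_n = 50) {
  n1 <- n1 %||% sample(1:max_n, 1)
  n0 <- n0 %||% sample(1:max_n, 1)
  # round to one decimal so ties occur regularly
  two_sample(
    cases = round(rnorm(n1, mean = 1), 1),
    controls = round(rnorm(n0), 1)
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

expect_nondecreasing <- function(values, tol = 1e-10) {
  expect_true(all(diff(values) >= -tol))
}
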