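test_that("pointwise MSE averages squared errors over replicates", {
  est <- rbind(c(0.4, 0.3), c(0.6, 0.3))
  expect_equal(pointwise_mse(est, truth = c(0.5, 0.3)), c(0.01, 0))
  expect_equal(pointwise_mse(matrix(0.5, 3, 4), rep(0.5, 4)), rep(0, 4))
  # pure bias: constant offset b gives b^2 everywhere
  b <- 0.07
  truth <- seq(0.1, 0.5, by = 0.1)
  est_b <- matrix(rep(truth + b, each = 6), nrow = 6, byrow = FALSE)
  expect_equal(pointwise_mse(est_b, truth), rep(b^2, 5))
  expect_error(pointwise_mse(est, truth = c(0.5)), "match")
})

test_that("relative efficiency is the reference-to-estimator MSE ratio", {
  ref <- c(0.02, 0.04)
  expect_equal(relative_efficiency(ref, ref), c(1, 1))
  expect_equal(relative_efficiency(ref / 4, ref), c(4, 4))
  expect_equal(relative_efficiency(ref * 2, ref), c(0.5, 0.5))
  expect_error(relative_efficiency(c(0, 0.1), ref), "degenerate")
})

test_that("MISE is the trapezoidal integral of the pointwise MSE", {
  grid <- seq(0.01, 0.99, by = 0.01)
  b <- 0.2
  est <- matrix(b, nrow = 1, ncol = length(grid))
  expect_equal(mise(est, rep(0, length(grid)), grid), b^2 * 0.98)
  # quadratic scaling: halving every error quarters the MISE
  set.seed(1)
  err <- matrix(runif(5 * length(grid), -0.2, 0.2), nrow = 5)
  truth <- rep(0.5, length(grid))
  expect_equal(mise(truth + err / 2, truth, grid),
               mise(truth + err, truth, grid) / 4)
  expect_equal(mise(est, rep(b, length(grid)), grid), 0)
})

test_that("overall relative efficiency is the MISE ratio", {
  expect_equal(overall_relative_efficiency(0.01, 0.01), 1)
  expect_equal(overall_relative_efficiency(0.005, 0.01), 2)
  expect_equal(overall_relative_efficiency(0.02, 0.01), 0.5)
  expect_error(overall_relative_efficiency(0, 0.01), "degenerate")
})

test_that("simulation runs are deterministic and score the reference at 1", {
  sim1 <- run_simulation("S1", n1 = 15, n0 = 15, replicates = 10, seed = 3)
  sim2 <- run_simulation("S1", n1 = 15, n0 = 15, replicates = 10, seed = 3)
  expect_identical(sim1$pointwise, sim2$pointwise)
  expect_identical(sim1$summary, sim2$summary)

  re_E <- sim1$pointwise$re[sim1$pointwise$estimator == "E"]
  expect_identical(re_E, rep(1, length(sim1$grid)))
  expect_equal(sim1$summary$ore[sim1$summary$estimator == "E"], 1)
  expect_true(all(sim1$pointwise$mse >= 0))
  expect_true(all(sim1$summary$mise >= 0))
})

test_that("an oracle estimator returning the true curve has zero error", {
  spec <- builtin_scenarios()$S1
  oracle <- function(data, grid) true_roc(spec, grid)
  sim <- run_simulation(spec, n1 = 10, n0 = 10, replicates = 5,
                        estimators = c(default_estimators()["E"],
                                       list(truth = oracle)),
                        seed = 4)
  mse_truth <- sim$pointwise$mse[sim$pointwise$estimator == "truth"]
  expect_equal(mse_truth, rep(0, length(sim$grid)))
  expect_equal(sim$summary$mise[sim$summary$estimator == "truth"], 0)
})

test_that("MISE equals the quadrature of the reported pointwise MSE", {
  sim <- run_simulation("S3", n1 = 12, n0 = 12, replicates = 8, seed = 5)
  for (nm in sim$summary$estimator) {
    m <- sim$pointwise$mse[sim$pointwise$estimator == nm]
    expect_equal(sim$summary$mise[sim$summary$estimator == nm],
                 pracma::trapz(sim$grid, m), tolerance = 1e-12)
  }
})

test_that("contract violations abort with the estimator named", {
  bad <- function(data, grid) rep(2, length(grid))
  expect_error(
    run_simulation("S1", replicates = 2, seed = 1,
                   estimators = c(default_estimators()["E"],
                                  list(bad = bad))),
    "`bad`.*outside \\[0, 1\\]"
  )
  short <- function(data, grid) grid[-1]
  expect_error(
    run_simulation("S1", replicates = 2, seed = 1,
                   estimators = c(default_estimators()["E"],
                                  list(short = short))),
    "`short`.*contract"
  )
  failing <- function(data, grid) stop("boom")
  expect_error(
    run_simulation("S1", replicates = 2, seed = 1,
                   estimators = c(default_estimators()["E"],
                                  list(failing = failing))),
    "`failing` failed on replicate 1"
  )
  expect_error(
    run_simulation("S1", replicates = 2, seed = 1,
                   estimators = default_estimators()[c("BP", "BPa")]),
    "must include the empirical reference"
  )
})

test_that("empirical MISE shrinks as both samples grow", {
  e_only <- default_estimators()["E"]
  small <- run_simulation("S1", n1 = 30, n0 = 30, replicates = 200,
                          estimators = e_only, seed = 6)
  large <- run_simulation("S1", n1 = 100, n0 = 100, replicates = 200,
                          estimators = e_only, seed = 6)
  expect_lt(large$summary$mise, small$summary$mise)
})
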