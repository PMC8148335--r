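#' Default estimator set for simulation runs
#'
#' An estimator is any named function `f(data, grid)` mapping a
#' [two_sample()] and a grid of false positive rates to curve values in
#' `[0, 1]` of the same length as the grid.  The default set holds the
#' empirical reference `E`, the two Bernstein smoothers `BP` and `BPa`,
#' and the binormal baseline `BN`.  Additional estimators can be appended
#' as plug-ins; the reference `E` must always be present because the
#' relative efficiency metrics are defined against it.
#'
#' @return A named list of estimator functions.
#' @export
default_estimators <- function() {
  list(
    E = function(data, grid) empirical_roc(data, grid),
    BP = function(data, grid) bp_evaluate(bp_fit(data), grid),
    BPa = function(data, grid) bp_evaluate(bpa_fit(data), grid),
    BN = function(data, grid) binormal_roc(data, grid)
  )
}

#' Monte Carlo comparison of ROC curve estimators
#'
#' Replicates the sampling of a scenario, evaluates each estimator on a
#' fixed grid of false positive rates, and scores every estimator against
#' the scenario's true ROC curve: pointwise mean squared error (MSE),
#' pointwise relative efficiency (RE) against the empirical reference,
#' mean integrated squared error (MISE, trapezoidal quadrature over the
#' grid) and overall relative efficiency (ORE = MISE of the empirical
#' estimator divided by the estimator's MISE; values above 1 mean more
#' efficient than the empirical curve).
#'
#' Per-replicate random streams are derived from the root `seed` before
#' any data are drawn, so adding or removing estimators does not change
#' the simulated samples, and reruns with the same seed are identical.
#' A failing estimator or an estimator returning values outside `[0, 1]`
#' aborts the run with a diagnostic naming the estimator and replicate;
#' no replicate is silently skipped.
#'
#' @param scenario A [scenario_spec()] or built-in name (`"S1"`..`"S6"`).
#' @param n1,n0 Case and control sample sizes per replicate.
#' @param replicates Number of Monte Carlo replicates `N`.
#' @param grid Strictly increasing false positive rates; the default is
#'   the 99-point grid 0.01, 0.02, ..., 0.99.
#' @param estimators Named list of estimator functions; must contain `E`.
#' @param seed Root integer seed.
#' @param verbose Print progress every 100 replicates.
#'
#' @return A `roc_simulation` object with elements `pointwise` (tibble:
#'   estimator, u, mse, re), `summary` (tibble: estimator, mise, ore) and
#'   the run metadata.
#' @examples
#' sim <- run_simulation("S1", n1 = 30, n0 = 30, replicates = 20, seed = 1)
#' sim$summary
#' @export
run_simulation <- function(scenario, n1 = 30, n0 = 30, replicates = 2000,
                           grid = seq(0.01, 0.99, by = 0.01),
                           estimators = default_estimators(),
                           seed = 1L, verbose = FALSE) {
  spec <- resolve_scenario(scenario)
  if (!is.numeric(replicates) || replicates < 1) {
    stop("`replicates` must be >= 1.", call. = FALSE)
  }
  check_prob(grid, "grid")
  if (any(diff(grid) <= 0)) {
    stop("`grid` must be strictly increasing.", call. = FALSE)
  }
  if (is.null(names(estimators)) || anyNA(names(estimators)) ||
      any(names(estimators) == "") || anyDuplicated(names(estimators))) {
    stop("`estimators` must be a uniquely named list of functions.",
         call. = FALSE)
  }
  if (!"E" %in% names(estimators)) {
    stop("`estimators` must include the empirical reference `E`.",
         call. = FALSE)
  }
  n_rep <- as.integer(replicates)
  n_grid <- length(grid)
  truth <- true_roc(spec, grid)

  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_rep)

  estimates <- lapply(estimators, function(e) {
    matrix(NA_real_, nrow = n_rep, ncol = n_grid)
  })
  for (k in seq_len(n_rep)) {
    set.seed(rep_seeds[k])
    dat <- sample_scenario(spec, n1, n0)
    for (nm in names(estimators)) {
      vals <- tryCatch(
        estimators[[nm]](dat, grid),
        error = function(e) {
          stop(sprintf("Estimator `%s` failed on replicate %d: %s",
                       nm, k, conditionMessage(e)), call. = FALSE)
        }
      )
      if (!is.numeric(vals) || length(vals) != n_grid) {
        stop(sprintf(
          "Estimator `%s` violated its contract on replicate %d: expected %d numeric values.",
          nm, k, n_grid), call. = FALSE)
      }
      if (any(vals < -1e-8) || any(vals > 1 + 1e-8)) {
        stop(sprintf(
          "Estimator `%s` returned values outside [0, 1] on replicate %d.",
          nm, k), call. = FALSE)
      }
      estimates[[nm]][k, ] <- pmin(pmax(vals, 0), 1)
    }
    if (verbose && k %% 100 == 0) {
      message(sprintf("  replicate %d/%d", k, n_rep))
    }
  }

  mse <- lapply(estimates, pointwise_mse, truth = truth)
  mise_all <- vapply(estimates, mise, numeric(1), truth = truth, grid = grid)
  # An exactly-zero MSE (e.g. an oracle estimator) gets infinite efficiency
  # rather than aborting the whole run.
  re <- lapply(mse, function(m) ifelse(m > 0, mse[["E"]] / m, Inf))
  ore <- vapply(mise_all, function(mi) {
    if (mi > 0) mise_all[["E"]] / mi else Inf
  }, numeric(1))

  est_names <- names(estimators)
  structure(
    list(
      pointwise = tibble(
        estimator = rep(est_names, each = n_grid),
        u = rep(grid, times = length(est_names)),
        mse = unlist(mse[est_names], use.names = FALSE),
        re = unlist(re[est_names], use.names = FALSE)
      ),
      summary = tibble(
        estimator = est_names,
        mise = unname(mise_all[est_names]),
        ore = unname(ore[est_names])
      ),
      scenario = spec, n1 = n1, n0 = n0, replicates = n_rep,
      grid = grid, seed = seed
    ),
    class = "roc_simulation"
  )
}

#' Simulation performance metrics
#'
#' @description
#' Scoring functions for replicated curve estimates on a fixed grid:
#'
#' * `pointwise_mse()` — mean over replicates of the squared error at each
#'   grid point.
#' * `relative_efficiency()` — ratio of the reference (empirical) MSE to an
#'   estimator's MSE at each grid point; values above 1 favour the
#'   estimator.
#' * `mise()` — mean integrated squared error: the trapezoidal integral of
#'   the pointwise MSE over the grid (averaging over replicates commutes
#'   with the quadrature, so this equals the mean of per-replicate
#'   integrated squared errors).
#' * `overall_relative_efficiency()` — ratio of the reference MISE to an
#'   estimator's MISE.
#'
#' @param estimates Numeric `N x G` matrix: one row per replicate, one
#'   column per grid point.
#' @param truth Numeric length-`G` vector of true curve values.
#' @param grid Numeric length-`G` vector of grid points.
#' @param mse_j,mse_ref Length-`G` pointwise MSE vectors (estimator and
#'   empirical reference).
#' @param mise_j,mise_ref Scalar MISE values.
#' @return `pointwise_mse()` and `relative_efficiency()` return length-`G`
#'   vectors; `mise()` and `overall_relative_efficiency()` return scalars.
#' @examples
#' est <- rbind(c(0.4, 0.5), c(0.6, 0.5))
#' pointwise_mse(est, truth = c(0.5, 0.5))  # 0.01, 0
#' @export
pointwise_mse <- function(estimates, truth) {
  estimates <- as.matrix(estimates)
  if (!is.numeric(estimates) || nrow(estimates) < 1L) {
    stop("`estimates` must be a numeric matrix with >= 1 row.",
         call. = FALSE)
  }
  if (length(truth) != ncol(estimates)) {
    stop("`truth` length must match the number of grid columns.",
         call. = FALSE)
  }
  colMeans(sweep(estimates, 2, truth)^2)
}

#' @rdname pointwise_mse
#' @export
relative_efficiency <- function(mse_j, mse_ref) {
  if (length(mse_j) != length(mse_ref)) {
    stop("MSE vectors must have equal length.", call. = FALSE)
  }
  if (any(mse_j <= 0)) {
    stop("Relative efficiency is degenerate: zero MSE in the denominator.",
         call. = FALSE)
  }
  mse_ref / mse_j
}

#' @rdname pointwise_mse
#' @export
mise <- function(estimates, truth, grid) {
  m <- pointwise_mse(estimates, truth)
  if (length(grid) != length(m)) {
    stop("`grid` length must match the number of grid columns.",
         call. = FALSE)
  }
  pracma::trapz(grid, m)
}

#' @rdname pointwise_mse
#' @export
overall_relative_efficiency <- function(mise_j, mise_ref) {
  if (mise_j <= 0) {
    stop("Overall relative efficiency is degenerate: non-positive MISE.",
         call. = FALSE)
  }
  mise_ref / mise_j
}

#' Per-estimator MISE and ORE of a simulation run
#'
#' @param sim A `roc_simulation` object.
#' @return A tibble with columns `estimator`, `mise`, `ore`.
#' @export
efficiency_summary <- function(sim) {
  if (!inherits(sim, "roc_simulation")) {
    stop("`sim` must be a roc_simulation.", call. = FALSE)
  }
  sim$summary
}

#' @export
print.roc_simulation <- function(x, ...) {
  cat(sprintf(
    "<roc_simulation> %s, n1 = %d, n0 = %d, N = %d replicates, seed %d\n",
    x$scenario$name, x$n1, x$n0, x$replicates, x$seed))
  print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}

#' @describeIn efficiency_summary Pointwise MSE/RE table (tibble:
#'   estimator, u, mse, re).
#' @param x A `roc_simulation` object.
#' @param ... Unused.
#' @method tidy roc_simulation
#' @export
tidy.roc_simulation <- function(x, ...) x$pointwise

#' @describeIn efficiency_summary One-row run summary with the most
#'   efficient estimator by ORE.
#' @method glance roc_simulation
#' @export
glance.roc_simulation <- function(x, ...) {
  best <- x$summary[which.max(x$summary$ore), ]
  tibble(
    scenario = x$scenario$name, n1 = x$n1, n0 = x$n0,
    replicates = x$replicates, n_estimators = nrow(x$summary),
    best_estimator = best$estimator, best_ore = best$ore
  )
}

#' @describeIn efficiency_summary Relative efficiency against the false
#'   positive rate, one line per estimator, with the ORE appended to the
#'   legend label and a reference line at RE = 1.
#' @param object A `roc_simulation` object.
#' @method autoplot roc_simulation
#' @export
autoplot.roc_simulation <- function(object, ...) {
  labels <- sprintf("%s (%.2f)", object$summary$estimator,
                    object$summary$ore)
  names(labels) <- object$summary$estimator
  dat <- dplyr::filter(object$pointwise, .data$estimator != "E")
  dat$estimator <- factor(dat$estimator,
                          levels = setdiff(object$summary$estimator, "E"))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$u, y = .data$re,
                                    colour = .data$estimator)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::scale_colour_discrete(labels = labels[levels(dat$estimator)]) +
    ggplot2::labs(
      x = "False positive rate u", y = "Relative efficiency",
      colour = "Estimator (ORE)",
      title = sprintf("%s: n1 = %d, n0 = %d, N = %d",
                      object$scenario$name, object$n1, object$n0,
                      object$replicates)
    ) +
    ggplot2::theme_minimal()
}
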