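#' Bernstein polynomial ROC fits
#'
#' @description
#' The Bernstein polynomial ROC estimator smooths the empirical ROC curve
#' with a Bernstein polynomial whose degree (the smoothing bandwidth) is
#' selected from the data:
#'
#' * `bp_fit()` — the BP rule.  The degree `m` is the number of unique
#'   control values; the node coefficients are the case survival fractions
#'   at the sorted unique control order statistics,
#'   `c_k = 1 - F1_hat(X_{0:k})`, with `X_{0:0} = -Inf` so `c_0 = 1`.  The
#'   fitted curve is `R(u) = sum_k choose(m,k) (1-u)^k u^(m-k) c_k`.
#' * `bp_general()` — an explicit degree `m`: the empirical ROC curve is
#'   evaluated on the uniform grid `j/m` and those values are smoothed with
#'   the Bernstein basis in `u` directly.
#' * `bpa_fit()` — the BPa rule: `bp_general()` with `m` equal to the
#'   number of steps of the empirical ROC curve including the endpoints
#'   (0,0) and (1,1); see [count_eroc_steps()].
#'
#' All three return a `bernstein_roc_fit` object; evaluate it with
#' [bp_evaluate()] or `predict()`.
#'
#' @param data A [two_sample()] or a data frame with value/label columns.
#' @param m Positive integer degree for `bp_general()`.
#' @param value,label Column names used when `data` is a data frame.
#'
#' @return An object of class `bernstein_roc_fit` with fields `degree`,
#'   `coefficients`, `bandwidth_rule` (`"BP"`, `"BPa"` or `"explicit"`) and
#'   `orientation` (`"step"` for the control-order-statistic construction,
#'   `"grid"` for uniform-grid node values).
#' @examples
#' d <- two_sample(cases = c(1.5, 3), controls = c(1, 2))
#' fit <- bp_fit(d)
#' fit$coefficients        # 1, 1, 0.5
#' bp_evaluate(fit, 0.5)   # 0.875
#' @export
bp_fit <- function(data, value = "value", label = "label") {
  ts <- ensure_two_sample(data, value, label)
  x0 <- sort(unique(ts$controls))
  m <- length(x0)
  coef <- c(1, 1 - empirical_cdf(ts$cases, x0))
  new_bernstein_roc_fit(
    degree = m, coefficients = coef,
    bandwidth_rule = "BP", orientation = "step",
    n1 = length(ts$cases), n0 = length(ts$controls)
  )
}

#' @rdname bp_fit
#' @export
bp_general <- function(data, m, value = "value", label = "label") {
  ts <- ensure_two_sample(data, value, label)
  if (!is.numeric(m) || length(m) != 1L || m < 1 || m != floor(m)) {
    stop("`m` must be a single integer >= 1.", call. = FALSE)
  }
  m <- as.integer(m)
  coef <- empirical_roc(ts, (0:m) / m)
  new_bernstein_roc_fit(
    degree = m, coefficients = coef,
    bandwidth_rule = "explicit", orientation = "grid",
    n1 = length(ts$cases), n0 = length(ts$controls)
  )
}

#' @rdname bp_fit
#' @export
bpa_fit <- function(data, value = "value", label = "label") {
  ts <- ensure_two_sample(data, value, label)
  fit <- bp_general(ts, count_eroc_steps(ts))
  fit$bandwidth_rule <- "BPa"
  fit
}

new_bernstein_roc_fit <- function(degree, coefficients, bandwidth_rule,
                                  orientation, n1, n0) {
  stopifnot(length(coefficients) == degree + 1L)
  structure(
    list(
      degree = as.integer(degree),
      coefficients = as.numeric(coefficients),
      bandwidth_rule = bandwidth_rule,
      orientation = orientation,
      n1 = n1, n0 = n0
    ),
    class = "bernstein_roc_fit"
  )
}

#' Evaluate a Bernstein polynomial ROC fit
#'
#' Computes the smoothed ROC value at each false positive rate `u`.  The
#' two coefficient orientations differ only by reversal of the coefficient
#' vector: a `"step"` fit attaches `c_k` to the basis in `1 - u`, a
#' `"grid"` fit attaches the node value `R(j/m)` to the basis in `u`.  The
#' result at `u = 1` is always 1 for fits built from data (the curve passes
#' through (1, 1) exactly).
#'
#' @param fit A `bernstein_roc_fit` from [bp_fit()], [bp_general()] or
#'   [bpa_fit()].
#' @param u Numeric vector of false positive rates in `[0, 1]`.
#' @return Numeric vector of ROC values; a convex combination of the
#'   coefficients, hence inside their range.
#' @export
bp_evaluate <- function(fit, u) {
  if (!inherits(fit, "bernstein_roc_fit")) {
    stop("`fit` must be a bernstein_roc_fit.", call. = FALSE)
  }
  check_prob(u)
  coef <- switch(fit$orientation,
    step = rev(fit$coefficients),
    grid = fit$coefficients,
    stop("Unknown coefficient orientation.", call. = FALSE)
  )
  bernstein_eval(coef, u)
}

#' @export
predict.bernstein_roc_fit <- function(object, u, ...) bp_evaluate(object, u)

#' @export
print.bernstein_roc_fit <- function(x, ...) {
  cat(sprintf("<bernstein_roc_fit> degree m = %d (%s rule)\n",
              x$degree, x$bandwidth_rule))
  cat(sprintf("  samples: n1 = %d cases, n0 = %d controls\n", x$n1, x$n0))
  cat("  coefficients: ",
      paste(signif(head(x$coefficients, 8), 4), collapse = ", "),
      if (x$degree + 1L > 8L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Number of steps of the empirical ROC curve
#'
#' Counts the steps of the empirical ROC staircase including the endpoints
#' (0,0) and (1,1): the number of distinct values among the case survival
#' fractions `c_k = 1 - F1_hat(X_{0:k})` over the unique control order
#' statistics (with `X_{0:0} = -Inf`), plus one if the 0 level — the point
#' (0,0) — is not attained.  The (1,1) level is always attained through
#' `c_0 = 1`.  This count is the BPa smoothing degree.
#'
#' @inheritParams bp_fit
#' @return An integer `>= 2`.
#' @examples
#' count_eroc_steps(two_sample(c(1.5, 3), c(1, 2)))  # 3
#' @export
count_eroc_steps <- function(data, value = "value", label = "label") {
  ts <- ensure_two_sample(data, value, label)
  x0 <- sort(unique(ts$controls))
  levels <- unique(c(1, 1 - empirical_cdf(ts$cases, x0)))
  length(levels) + as.integer(!any(levels == 0))
}
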