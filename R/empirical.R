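#' Empirical distribution function
#'
#' Right-continuous empirical CDF: the proportion of sample values less
#' than or equal to `x`.  Ties are counted with `<=`.
#'
#' @param sample Non-empty numeric vector.
#' @param x Numeric vector of evaluation points (finite).
#' @return Numeric vector of proportions in `[0, 1]`, one per element of `x`.
#' @examples
#' empirical_cdf(c(-0.5, 0.2, 1.1), 0.2)  # 2/3
#' @export
empirical_cdf <- function(sample, x) {
  check_sample(sample, "sample")
  if (!is.numeric(x) || !all(is.finite(x))) {
    stop("`x` must be numeric and finite.", call. = FALSE)
  }
  stats::ecdf(sample)(x)
}

#' Empirical quantile function
#'
#' The sample quantile convention used throughout the package: the order
#' statistic with index `floor(n * u) + 1`, clamped to `n` at `u = 1`, so
#' the quantile always lies between the sample minimum and maximum.  This
#' convention differs from the interpolating types of [stats::quantile()].
#'
#' @param sample Non-empty numeric vector.
#' @param u Numeric vector of probabilities in `[0, 1]`.
#' @return Numeric vector of order statistics, one per element of `u`.
#' @examples
#' empirical_quantile(c(10, 20, 30, 40), 0.5)  # 30
#' @export
empirical_quantile <- function(sample, u) {
  check_sample(sample, "sample")
  check_prob(u)
  n <- length(sample)
  sorted <- sort(sample)
  idx <- pmin(floor(n * u) + 1L, n)
  sorted[idx]
}

check_prob <- function(u, name = "u") {
  if (!is.numeric(u) || anyNA(u) || any(u < 0) || any(u > 1)) {
    stop(sprintf("`%s` must lie in [0, 1].", name), call. = FALSE)
  }
  invisible(u)
}

#' Empirical ROC curve
#'
#' The staircase plug-in estimator of the ROC curve,
#' `R(u) = 1 - F1(Q0(1 - u))`, composing the empirical CDF of the cases
#' with the empirical quantile function of the controls.  At a false
#' positive rate `u` it equals one minus the fraction of cases at or below
#' the selected control order statistic.
#'
#' @param data A [two_sample()] object or a data frame with value/label
#'   columns (see [as_two_sample()]).
#' @param u Numeric vector of false positive rates in `[0, 1]`.
#' @param value,label Column names used when `data` is a data frame.
#' @return Numeric vector of sensitivities in `[0, 1]`.
#' @examples
#' d <- two_sample(cases = c(1.5, 3), controls = c(1, 2))
#' empirical_roc(d, c(0, 0.5, 1))
#' @export
empirical_roc <- function(data, u, value = "value", label = "label") {
  ts <- ensure_two_sample(data, value, label)
  check_prob(u)
  thresholds <- empirical_quantile(ts$controls, 1 - u)
  1 - empirical_cdf(ts$cases, thresholds)
}
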