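#' Binormal ROC baseline
#'
#' The classical binormal ROC model `R(u) = pnorm(a + b * qnorm(u))` with
#' intercept `a = (mean(cases) - mean(controls)) / sd(cases)` and slope
#' `b = sd(controls) / sd(cases)`, the moments estimated by the sample mean
#' and sample standard deviation.  The endpoints are `R(0) = 0` and
#' `R(1) = 1` by continuity.  No Box-Cox transformation is applied.
#'
#' @inheritParams bp_fit
#' @param u Numeric vector of false positive rates in `[0, 1]`.
#' @return `binormal_roc()`: numeric vector of ROC values.
#'   `binormal_params()`: named list with `a` and `b`.
#' @examples
#' d <- two_sample(cases = 1 + c(-1, 1) * sqrt(0.5),
#'                 controls = c(-1, 1) * sqrt(0.5))
#' binormal_roc(d, 0.5)  # pnorm(1)
#' @export
binormal_roc <- function(data, u, value = "value", label = "label") {
  p <- binormal_params(data, value, label)
  check_prob(u)
  pnorm(p$a + p$b * qnorm(u))
}

#' @rdname binormal_roc
#' @export
binormal_params <- function(data, value = "value", label = "label") {
  ts <- ensure_two_sample(data, value, label)
  if (length(ts$cases) < 2L || length(ts$controls) < 2L) {
    stop("Binormal fit needs at least 2 values in each group.", call. = FALSE)
  }
  s1 <- sd(ts$cases)
  s0 <- sd(ts$controls)
  if (s1 <= 0 || s0 <= 0) {
    stop("Binormal fit is degenerate: zero variance in a group.",
         call. = FALSE)
  }
  list(a = (mean(ts$cases) - mean(ts$controls)) / s1, b = s0 / s1)
}
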