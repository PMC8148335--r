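#' Area under an ROC curve by trapezoidal integration
#'
#' Integrates an evaluated ROC curve over the false positive rate.  If the
#' grid does not reach 0 or 1 the curve is extended horizontally with the
#' endpoint grid values before integrating, and the result is clamped to
#' `[0, 1]`.
#'
#' @param curve A data frame with columns `u` (strictly increasing false
#'   positive rates in `[0, 1]`) and `r` (curve values in `[0, 1]`), as
#'   produced by [roc_curve()].
#' @return A single number in `[0, 1]`.
#' @examples
#' auc_from_curve(data.frame(u = c(0, 1), r = c(0, 1)))  # 0.5
#' @export
auc_from_curve <- function(curve) {
  if (!is.data.frame(curve) && !is.list(curve)) {
    stop("`curve` must be a data frame with columns `u` and `r`.",
         call. = FALSE)
  }
  u <- curve$u
  r <- curve$r
  if (is.null(u) || is.null(r) || length(u) != length(r)) {
    stop("`curve` must have `u` and `r` of equal length.", call. = FALSE)
  }
  if (length(u) < 2L) {
    stop("`curve` needs at least 2 grid points.", call. = FALSE)
  }
  check_prob(u, "u")
  if (any(diff(u) <= 0)) {
    stop("Grid `u` must be strictly increasing.", call. = FALSE)
  }
  if (u[1] > 0) { u <- c(0, u); r <- c(r[1], r) }
  n <- length(u)
  if (u[n] < 1) { u <- c(u, 1); r <- c(r, r[n]) }
  min(max(pracma::trapz(u, r), 0), 1)
}
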