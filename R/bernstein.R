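#' Bernstein basis weight
#'
#' The binomial probability mass `choose(n, j) * u^j * (1 - u)^(n - j)`,
#' the weight attached to the node `j/n` in a degree-`n` Bernstein
#' polynomial.  Computed in log space so that degrees of 10^4 and beyond
#' neither overflow nor underflow.
#'
#' @param j Integer index (or vector), `0 <= j <= n`.
#' @param n Non-negative integer degree.
#' @param u Numeric vector of points in `[0, 1]`.  `j` and `u` are recycled
#'   against each other.
#' @return Numeric vector of weights in `[0, 1]`.
#' @examples
#' bernstein_weight(1, 2, 0.5)              # 0.5
#' sum(bernstein_weight(0:5, 5, 0.3))       # 1
#' @export
bernstein_weight <- function(j, n, u) {
  if (!is.numeric(n) || length(n) != 1L || n < 0 || n != floor(n)) {
    stop("`n` must be a single non-negative integer.", call. = FALSE)
  }
  if (any(j != floor(j)) || any(j < 0) || any(j > n)) {
    stop("`j` must be an integer in 0..n.", call. = FALSE)
  }
  check_prob(u)
  exp(lchoose(n, j) + xlogy(j, u) + xlogy(n - j, 1 - u))
}

# a * log(b) with the convention 0 * log(0) = 0 (limit of the basis at the
# endpoints).
xlogy <- function(a, b) {
  out <- a * log(b)
  out[a == 0] <- 0
  out
}

# Evaluate the Bernstein polynomial with node values `coef` (coef[j + 1]
# belongs to node j/m, j = 0..m) at the points u.
bernstein_eval <- function(coef, u) {
  m <- length(coef) - 1L
  if (m == 0L) return(rep(coef, length(u)))
  j <- 0:m
  lw <- lchoose(m, j)
  vapply(
    u,
    function(ui) sum(exp(lw + xlogy(j, ui) + xlogy(m - j, 1 - ui)) * coef),
    numeric(1)
  )
}
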