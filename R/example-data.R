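# Worked-example dataset: 30 case values simulated from Normal(1, 1) and
# 30 control values from Normal(0, 1).  The same data ship as
# inst/extdata/example_markers.csv for command line use.
example_cases <- c(
  -1.661, 0.945, 0.495, 0.473, 1.498, 1.011, 0.682, 1.943, -0.543, 0.188,
  0.835, 2.976, 1.465, 2.056, 3.178, 0.619, 2.09, 0.551, 2.296, 2.373,
  0.637, 1.196, -0.049, 0.169, 0.809, 0.735, 1.844, 1.446, 1.093, -0.531
)

example_controls <- c(
  -0.417, -0.763, -0.9, -0.65, -0.396, -0.737, 0.827, -0.406, 0.614, 0.065,
  -1.46, 1.018, -0.824, 0.755, -0.539, -0.819, 0.399, -0.384, -0.203, 1.148,
  0.658, 0.7, -0.632, 1.569, -0.72, 2.378, -0.49, -1.16, 1.779, -0.152
)

#' Worked-example marker data
#'
#' A simulated diagnostic-marker dataset with 30 cases drawn from
#' Normal(1, 1) and 30 controls drawn from Normal(0, 1), bundled so the
#' estimators can be demonstrated against a known truth (the true ROC
#' curve of this design is the binormal curve `pnorm(1 + qnorm(u))`).
#'
#' @param format `"tibble"` (default; columns `value`, `label` with
#'   1 = case) or `"two_sample"`.
#' @return A tibble or a [two_sample()] with `n1 = n0 = 30`.
#' @examples
#' example_markers()
#' glance(roc_fit(example_markers(), "BP"))
#' @export
example_markers <- function(format = c("tibble", "two_sample")) {
  format <- match.arg(format)
  ts <- two_sample(cases = example_cases, controls = example_controls)
  if (format == "two_sample") ts else as_tibble(ts)
}
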