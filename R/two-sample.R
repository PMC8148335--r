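#' Bundle case and control marker values
#'
#' A `two_sample` object holds the diagnostic marker measurements of the
#' diseased (case) group and the non-diseased (control) group.  All curve
#' estimators in the package accept either a `two_sample` or a data frame
#' with a value column and a binary label column (see [as_two_sample()]).
#'
#' @param cases Numeric vector of marker values for the diseased group
#'   (length `n1 >= 1`, all finite).  Ties are allowed.
#' @param controls Numeric vector of marker values for the non-diseased
#'   group (length `n0 >= 1`, all finite).
#'
#' @return An object of class `two_sample`: a list with elements `cases`
#'   and `controls`.
#' @examples
#' two_sample(cases = c(1.5, 3), controls = c(1, 2))
#' @export
two_sample <- function(cases, controls) {
  check_sample(cases, "cases")
  check_sample(controls, "controls")
  structure(
    list(cases = as.numeric(cases), controls = as.numeric(controls)),
    class = "two_sample"
  )
}

check_sample <- function(x, name) {
  if (!is.numeric(x) || length(x) < 1L) {
    stop(sprintf("`%s` must be a non-empty numeric vector.", name),
         call. = FALSE)
  }
  if (!all(is.finite(x))) {
    stop(sprintf("`%s` contains non-finite values (rows: %s).",
                 name, paste(which(!is.finite(x)), collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}

#' Convert a data frame of marker values and labels to a two_sample
#'
#' Rows with label 1 become cases and rows with label 0 become controls.
#'
#' @param data A data frame.
#' @param value Name of the numeric marker column.  Default `"value"`.
#' @param label Name of the binary (0/1) group column.  Default `"label"`.
#'
#' @return A [two_sample()] object.
#' @examples
#' df <- data.frame(value = c(1.5, 3, 1, 2), label = c(1, 1, 0, 0))
#' as_two_sample(df)
#' @export
as_two_sample <- function(data, value = "value", label = "label") {
  if (inherits(data, "two_sample")) return(data)
  if (!is.data.frame(data)) {
    stop("`data` must be a data frame or a two_sample object.", call. = FALSE)
  }
  missing_cols <- setdiff(c(value, label), names(data))
  if (length(missing_cols)) {
    stop(sprintf("Column(s) not found in `data`: %s.",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  v <- data[[value]]
  l <- data[[label]]
  if (is.logical(l)) l <- as.integer(l)
  if (!is.numeric(v)) {
    stop(sprintf("Column `%s` must be numeric.", value), call. = FALSE)
  }
  bad <- which(!is.finite(v))
  if (length(bad)) {
    stop(sprintf("Non-finite or missing marker values in rows: %s.",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (!all(l %in% c(0, 1))) {
    stop(sprintf("Label column `%s` must be binary 0/1 (1 = case).", label),
         call. = FALSE)
  }
  if (!any(l == 1)) stop("No case rows (label 1) in `data`.", call. = FALSE)
  if (!any(l == 0)) stop("No control rows (label 0) in `data`.", call. = FALSE)
  two_sample(cases = v[l == 1], controls = v[l == 0])
}

# Accept a two_sample or a data frame anywhere an estimator takes data.
ensure_two_sample <- function(data, value = "value", label = "label") {
  if (inherits(data, "two_sample")) data else as_two_sample(data, value, label)
}

#' @export
print.two_sample <- function(x, ...) {
  cat(sprintf("<two_sample> %d cases, %d controls\n",
              length(x$cases), length(x$controls)))
  cat(sprintf("  cases:    [%.4g, %.4g]\n", min(x$cases), max(x$cases)))
  cat(sprintf("  controls: [%.4g, %.4g]\n", min(x$controls), max(x$controls)))
  invisible(x)
}

#' @method as_tibble two_sample
#' @export
as_tibble.two_sample <- function(x, ...) {
  tibble(
    value = c(x$cases, x$controls),
    label = rep(c(1L, 0L), c(length(x$cases), length(x$controls)))
  )
}
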