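#' Fit an ROC curve estimator to case/control data
#'
#' Data-frame-first front end to the package's estimators.  The input is a
#' table of marker values with a binary label (1 = case), or a
#' [two_sample()] object; the result is a fitted object that can be
#' evaluated on a grid ([roc_curve()]), summarised ([glance()], [tidy()])
#' and plotted ([autoplot()]).
#'
#' Available methods (aliases in parentheses):
#' * `"empirical"` (`"E"`) — the staircase plug-in estimator.
#' * `"bp"` (`"BP"`) — Bernstein polynomial smoothing, degree = number of
#'   unique control values.
#' * `"bpa"` (`"BPa"`) — Bernstein polynomial smoothing, degree = number of
#'   steps of the empirical ROC curve.
#' * `"binormal"` (`"BN"`) — the moment-based binormal model.
#'
#' @param data A data frame with value/label columns or a [two_sample()].
#' @param method Estimator name or alias (see above).
#' @param value,label Column names used when `data` is a data frame.
#' @param m Optional explicit Bernstein degree; when supplied, overrides
#'   the automatic bandwidth and fits [bp_general()].
#'
#' @return An object of class `roc_fit`.
#' @examples
#' fit <- roc_fit(example_markers(), method = "BP")
#' glance(fit)
#' @export
roc_fit <- function(data, method = c("empirical", "bp", "bpa", "binormal"),
                    value = "value", label = "label", m = NULL) {
  ts <- ensure_two_sample(data, value, label)
  method <- normalize_method(if (is.character(method)) method[1] else method)
  fit <- if (!is.null(m)) {
    if (!method %in% c("bp", "bpa")) {
      stop("`m` is only meaningful for Bernstein methods.", call. = FALSE)
    }
    bp_general(ts, m)
  } else {
    switch(method,
      empirical = NULL,
      bp = bp_fit(ts),
      bpa = bpa_fit(ts),
      binormal = binormal_params(ts)
    )
  }
  structure(
    list(method = method, label = method_label(method), data = ts, fit = fit),
    class = "roc_fit"
  )
}

normalize_method <- function(method) {
  key <- c(
    empirical = "empirical", e = "empirical",
    bp = "bp", bpa = "bpa",
    binormal = "binormal", bn = "binormal"
  )
  out <- unname(key[tolower(method)])
  if (is.na(out)) {
    stop(sprintf("Unknown estimator `%s`. Choose one of: E, BP, BPa, BN.",
                 method), call. = FALSE)
  }
  out
}

method_label <- function(method) {
  c(empirical = "E", bp = "BP", bpa = "BPa", binormal = "BN")[[method]]
}

#' @export
predict.roc_fit <- function(object, u, ...) {
  check_prob(u)
  switch(object$method,
    empirical = empirical_roc(object$data, u),
    bp = ,
    bpa = bp_evaluate(object$fit, u),
    binormal = pnorm(object$fit$a + object$fit$b * qnorm(u))
  )
}

#' Evaluate a fitted ROC estimator on a grid
#'
#' @param fit A `roc_fit` object.
#' @param grid Strictly increasing false positive rates in `[0, 1]`.
#'   Defaults to 1001 equally spaced points from 0 to 1.
#' @return A tibble with columns `u` and `r`.
#' @export
roc_curve <- function(fit, grid = seq(0, 1, length.out = 1001)) {
  if (!inherits(fit, "roc_fit")) {
    stop("`fit` must be a roc_fit object.", call. = FALSE)
  }
  tibble(u = grid, r = predict(fit, grid))
}

#' @export
print.roc_fit <- function(x, ...) {
  cat(sprintf("<roc_fit> method %s, %d cases / %d controls\n",
              x$label, length(x$data$cases), length(x$data$controls)))
  if (inherits(x$fit, "bernstein_roc_fit")) {
    cat(sprintf("  Bernstein degree m = %d\n", x$fit$degree))
  }
  if (x$method == "binormal") {
    cat(sprintf("  a = %.4f, b = %.4f\n", x$fit$a, x$fit$b))
  }
  invisible(x)
}

#' @describeIn roc_fit Coefficient-level summary: Bernstein node
#'   coefficients, binormal intercept/slope, or the staircase vertices of
#'   the empirical estimator.
#' @param x,object A `roc_fit` object.
#' @param ... Unused.
#' @method tidy roc_fit
#' @export
tidy.roc_fit <- function(x, ...) {
  switch(x$method,
    bp = ,
    bpa = tibble(index = 0:x$fit$degree, coefficient = x$fit$coefficients),
    binormal = tibble(term = c("intercept", "slope"),
                      estimate = c(x$fit$a, x$fit$b)),
    empirical = {
      u_steps <- sort(unique(c(
        0, 1, 1 - empirical_cdf(x$data$controls, sort(unique(x$data$controls)))
      )))
      tibble(u = u_steps, r = empirical_roc(x$data, u_steps))
    }
  )
}

#' @describeIn roc_fit One-row summary with sample sizes, selected degree
#'   and trapezoidal AUC (1001-point grid).
#' @method glance roc_fit
#' @export
glance.roc_fit <- function(x, ...) {
  tibble(
    method = x$label,
    n1 = length(x$data$cases),
    n0 = length(x$data$controls),
    degree = if (inherits(x$fit, "bernstein_roc_fit")) x$fit$degree
             else NA_integer_,
    auc = auc_from_curve(roc_curve(x))
  )
}

#' @describeIn roc_fit Plot the fitted curve against the chance diagonal.
#' @param grid Evaluation grid for plotting.
#' @method autoplot roc_fit
#' @export
autoplot.roc_fit <- function(object, grid = seq(0, 1, length.out = 1001),
                             ...) {
  curve <- roc_curve(object, grid)
  geom <- if (object$method == "empirical") ggplot2::geom_step
          else ggplot2::geom_line
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$u, y = .data$r)) +
    ggplot2::geom_abline(slope = 1, intercept = 0,
                         linetype = "dashed", colour = "grey60") +
    geom(colour = "#2c6e91", linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate (1 - specificity)",
      y = "True positive rate (sensitivity)",
      title = sprintf("%s ROC estimate", object$label)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
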