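#' Read case/control marker data from a delimited text file
#'
#' The file must hold one numeric marker column and one binary label
#' column (1 = case/diseased, 0 = control).  Non-numeric or missing marker
#' cells are reported with their row numbers.
#'
#' @param path Path to a CSV (or TSV, with `delim = "\t"`) file.
#' @param value_column,label_column Column names.  Defaults `"value"` and
#'   `"label"`.
#' @param delim Field delimiter; default `","`.
#' @return A [two_sample()] object.
#' @export
read_two_sample_csv <- function(path, value_column = "value",
                                label_column = "label", delim = ",") {
  if (!file.exists(path)) {
    stop(sprintf("Input file not found: %s", path), call. = FALSE)
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  missing_cols <- setdiff(c(value_column, label_column), names(raw))
  if (length(missing_cols)) {
    stop(sprintf("Column(s) missing from %s: %s.", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  values <- suppressWarnings(as.numeric(raw[[value_column]]))
  bad <- which(!is.finite(values))
  if (length(bad)) {
    stop(sprintf("Non-numeric or missing values in column `%s`, row(s): %s.",
                 value_column, paste(bad, collapse = ", ")), call. = FALSE)
  }
  labels <- suppressWarnings(as.numeric(raw[[label_column]]))
  if (anyNA(labels) || !all(labels %in% c(0, 1))) {
    stop(sprintf("Column `%s` must contain only 0 (control) and 1 (case).",
                 label_column), call. = FALSE)
  }
  df <- tibble(value = values, label = labels)
  ts <- as_two_sample(df)
  message(sprintf("Read %d cases and %d controls from %s.",
                  length(ts$cases), length(ts$controls), path))
  ts
}

#' Write case/control marker data to CSV
#'
#' Values are written with shortest round-trip precision, so reading the
#' file back reproduces the samples exactly.
#'
#' @param data A [two_sample()] or a data frame with value/label columns.
#' @param path Output path.
#' @param value_column,label_column Column names to write.
#' @return `path`, invisibly.
#' @export
write_two_sample_csv <- function(data, path, value_column = "value",
                                 label_column = "label") {
  ts <- ensure_two_sample(data)
  df <- as_tibble(ts)
  names(df) <- c(value_column, label_column)
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Write an evaluated ROC curve to CSV
#'
#' @param curve A data frame with columns `u` and `r` ([roc_curve()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  readr::write_csv(curve[, c("u", "r")], path, progress = FALSE)
  invisible(path)
}

#' Write a fit summary (degree, bandwidth rule, coefficients, AUC) as JSON
#'
#' @param fit A `roc_fit` object.
#' @param path Output path.
#' @param grid Grid used for the AUC computation.
#' @return The summary list, invisibly.
#' @export
write_fit_summary_json <- function(fit, path,
                                   grid = seq(0, 1, length.out = 1001)) {
  if (!inherits(fit, "roc_fit")) {
    stop("`fit` must be a roc_fit object.", call. = FALSE)
  }
  summary <- list(
    estimator = fit$label,
    n1 = length(fit$data$cases),
    n0 = length(fit$data$controls),
    auc = auc_from_curve(roc_curve(fit, grid))
  )
  if (inherits(fit$fit, "bernstein_roc_fit")) {
    summary$degree <- fit$fit$degree
    summary$bandwidth_rule <- fit$fit$bandwidth_rule
    summary$coefficients <- fit$fit$coefficients
  }
  if (fit$method == "binormal") {
    summary$intercept <- fit$fit$a
    summary$slope <- fit$fit$b
  }
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA)
  invisible(summary)
}
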