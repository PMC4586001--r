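#' QALYs by area under the utility curve
#'
#' Converts a patient's utility trajectory, measured at fixed timepoints in
#' months, into quality-adjusted life years by linear interpolation between
#' observations: the area under the piecewise-linear utility curve, divided
#' by 12 to express months as years. With measurements at 0, 2 and 5
#' months the horizon is 5 months, so QALYs lie in \[0, 5/12\].
#'
#' @param utilities Numeric vector of utilities in \[0, 1\], one per
#'   timepoint, no missing values (impute first; see [impute_chained()]).
#' @param times Measurement times in months, strictly increasing, starting
#'   at 0 (baseline). Default `c(0, 2, 5)`: baseline, end of the 2-month
#'   intervention, end of follow-up.
#' @return QALYs (years).
#' @export
#' @examples
#' qaly_auc(c(0.720, 0.771, 0.788))  # 0.319 over 5 months
qaly_auc <- function(utilities, times = c(0, 2, 5)) {
  if (length(times) < 2 || length(utilities) != length(times))
    abort("need utilities at >= 2 timepoints (one value per timepoint)",
          class = "cueval_validation_error", field = "times")
  if (anyNA(utilities))
    abort("utilities contain missing values; impute first (impute_chained() or impute_locf())",
          class = "cueval_validation_error", field = "utilities")
  if (any(diff(times) <= 0))
    abort("times must be strictly increasing",
          class = "cueval_validation_error", field = "times")
  if (times[1] != 0)
    abort("first measurement time must be baseline (0 months)",
          class = "cueval_validation_error", field = "times")
  if (any(utilities < 0 | utilities > 1))
    abort("utilities outside [0, 1]; SF-6D utilities never leave this range, so this signals data corruption",
          class = "cueval_validation_error", field = "utilities")
  k <- length(times)
  sum(diff(times) * (utilities[-k] + utilities[-1]) / 2) / 12
}

#' Add a per-patient QALY column
#'
#' Vectorised [qaly_auc()] over the utility columns of a patient table.
#'
#' @param records Patient tibble with complete utility columns.
#' @param cols Utility column names, in time order (default
#'   `c("u0", "u2", "u5")`).
#' @param times Measurement times in months matching `cols`.
#' @return `records` with a `qaly` column added.
#' @export
add_qaly <- function(records, cols = c("u0", "u2", "u5"), times = c(0, 2, 5)) {
  miss <- setdiff(cols, names(records))
  if (length(miss))
    abort(sprintf("missing utility column(s): %s", paste(miss, collapse = ", ")),
          class = "cueval_validation_error", field = miss[1])
  U <- as.matrix(records[, cols, drop = FALSE])
  if (anyNA(U))
    abort("utilities contain missing values; impute first (impute_chained() or impute_locf())",
          class = "cueval_validation_error", field = "utilities")
  if (any(U < 0 | U > 1))
    abort("utilities outside [0, 1]",
          class = "cueval_validation_error", field = "utilities")
  if (any(diff(times) <= 0) || times[1] != 0)
    abort("times must be strictly increasing from baseline 0",
          class = "cueval_validation_error", field = "times")
  k <- length(times)
  w <- numeric(k)
  dt <- diff(times)
  w[1] <- dt[1] / 2
  w[k] <- dt[k - 1] / 2
  if (k > 2) w[2:(k - 1)] <- (dt[-(k - 1)] + dt[-1]) / 2
  records$qaly <- as.numeric(U %*% w) / 12
  records
}
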