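#' Summary of prediction errors
#'
#' Computes the full set of reporting metrics over deviations
#' `predicted - observed`: mean absolute error, root mean squared error,
#' maximum absolute error, within-threshold accuracy for each requested
#' threshold, and boxplot statistics (type-7 quartiles, IQR, and outliers
#' beyond the 1.5 IQR whiskers).
#'
#' @param predicted,observed Equal-length numeric vectors in cm.
#' @param thresholds Accuracy thresholds in cm (default `c(1, 2, 3)`).
#' @return An object of class `error_summary` with fields `n`, `mae`,
#'   `rmse`, `max_abs`, `within` (named fractions), `quartiles`
#'   (`q1, median, q3`), `iqr` and `outliers`.
#' @details Quartiles use linear interpolation between order statistics
#'   (R's default quantile type 7); the convention is stated because IQR
#'   and outlier sets depend on it.  `within` fractions are computed on
#'   `|deviation| < threshold` — a deviation sitting exactly on the
#'   threshold counts as a miss (for continuous errors the two conventions
#'   agree almost surely).  `within` is non-decreasing in the threshold and
#'   `mae <= rmse` always.
#' @export
#' @examples
#' s <- summarize_errors(c(171, 159, 172), c(170, 160, 170), thresholds = 2)
#' s$mae   # 4/3
#' s$rmse  # sqrt(2)
summarize_errors <- function(predicted, observed, thresholds = c(1, 2, 3)) {
  if (length(predicted) == 0L) stopf("empty input")
  if (length(predicted) != length(observed))
    stopf("predicted and observed differ in length")
  dev <- predicted - observed
  if (any(!is.finite(dev))) stopf("non-finite deviations")
  q <- unname(stats::quantile(dev, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[3] + 1.5 * iqr
  within <- vapply(thresholds, function(k) mean(abs(dev) < k), 0)
  names(within) <- paste0("within_", thresholds, "cm")
  structure(list(n = length(dev),
                 mae = mean(abs(dev)),
                 rmse = sqrt(mean(dev^2)),
                 max_abs = max(abs(dev)),
                 within = within,
                 quartiles = c(q1 = q[1], median = q[2], q3 = q[3]),
                 iqr = iqr,
                 outliers = dev[dev < lo | dev > hi],
                 deviations = dev),
            class = "error_summary")
}

#' @export
print.error_summary <- function(x, ...) {
  cat(sprintf("Error summary over n = %d predictions\n", x$n))
  cat(sprintf("  MAE %.3f cm   RMSE %.3f cm   max |error| %.3f cm\n",
              x$mae, x$rmse, x$max_abs))
  for (nm in names(x$within))
    cat(sprintf("  %s accuracy: %.2f%%\n", sub("_", " ", nm),
                100 * x$within[[nm]]))
  cat(sprintf("  quartiles (type 7): %.3f / %.3f / %.3f, IQR %.3f, %d outlier(s)\n",
              x$quartiles[1], x$quartiles[2], x$quartiles[3], x$iqr,
              length(x$outliers)))
  invisible(x)
}

#' Per-record deviation table
#'
#' Builds the standard worked-example layout: one row per record with the
#' observed target height, the predicted height, and their deviation
#' `predicted - observed`, rounded half-away-from-zero to 2 decimals for
#' display while the unrounded deviations are returned alongside.
#'
#' @param records Data frame with numeric columns `target_height` and
#'   `prediction_height` (extra columns are carried through).
#' @return The input data frame with columns `deviation` (display-rounded)
#'   and `deviation_exact` appended.
#' @export
deviation_table <- function(records) {
  records <- as.data.frame(records)
  need <- c("target_height", "prediction_height")
  missing <- setdiff(need, names(records))
  if (length(missing))
    stopf("records lack column(s): %s", paste(missing, collapse = ", "))
  if (anyNA(records[need])) stopf("missing target or prediction heights")
  dev <- records$prediction_height - records$target_height
  records$deviation_exact <- dev
  records$deviation <- round_half_away(dev, 2)
  records
}

#' Write an error-summary report as JSON
#'
#' @param summary An `error_summary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_error_report <- function(summary, path) {
  if (!inherits(summary, "error_summary"))
    stopf("`summary` must be an error_summary")
  jsonlite::write_json(
    list(n = summary$n, mae = summary$mae, rmse = summary$rmse,
         max_abs = summary$max_abs, within = as.list(summary$within),
         quartiles = as.list(summary$quartiles), iqr = summary$iqr,
         outliers = summary$outliers),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
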