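#' Load a height reference table (0 SD column)
#'
#' Reads a per-sex grid of mean ("0 SD") height against age from a CSV file
#' with columns `age` and `height`.  This grid plays the role of a national
#' growth reference; a synthetic example ships with the package (see
#' `system.file("extdata", package = "staturecast")`).
#'
#' @param path Path to a CSV file with numeric columns `age` (years) and
#'   `height` (cm), one header row, no missing cells.
#' @param sex `"male"` or `"female"`; stored with the table so downstream
#'   models are keyed by sex.
#' @return An object of class `reference_table` with fields `sex`, `ages`
#'   and `heights`, sorted by age.
#' @details Duplicate ages, non-numeric cells, missing values and tables
#'   with fewer than two rows are rejected.  Heights must be positive.
#' @seealso [fit_mean_curve()]
#' @export
#' @examples
#' ref <- load_reference_table(
#'   system.file("extdata", "reference_0sd_male_synthetic.csv",
#'               package = "staturecast"), sex = "male")
#' ref
load_reference_table <- function(path, sex) {
  sex <- check_sex(sex)
  df <- read_strict_csv(path, c("age", "height"), "reference")
  reference_table(df$age, df$height, sex)
}

#' Construct a height reference table from vectors
#'
#' @param ages Ages in years.
#' @param heights Mean heights in cm, same length as `ages`.
#' @param sex `"male"` or `"female"`.
#' @return A `reference_table` object.
#' @export
reference_table <- function(ages, heights, sex) {
  sex <- check_sex(sex)
  if (!is.numeric(ages) || !is.numeric(heights) ||
      anyNA(ages) || anyNA(heights))
    stopf("reference table must be numeric with no missing cells")
  if (length(ages) < 2L)
    stopf("reference table needs at least 2 rows, got %d", length(ages))
  if (length(ages) != length(heights))
    stopf("ages and heights differ in length")
  ord <- order(ages)
  ages <- ages[ord]; heights <- heights[ord]
  if (any(diff(ages) <= 0))
    stopf("reference ages must be strictly increasing (duplicate or tied age)")
  if (any(heights <= 0))
    stopf("reference heights must be positive")
  structure(list(sex = sex, ages = as.numeric(ages),
                 heights = as.numeric(heights)),
            class = "reference_table")
}

#' @export
print.reference_table <- function(x, ...) {
  cat(sprintf("Height reference table (%s): %d ages from %g to %g years\n",
              x$sex, length(x$ages), min(x$ages), max(x$ages)))
  invisible(x)
}

# Expand a polynomial in z = (x - ctr)/scl (coefficients lowest power first)
# into the raw-age basis, also lowest power first.
rebase_poly <- function(zco, ctr, scl) {
  out <- 0
  lin <- c(-ctr / scl, 1 / scl)      # z as a polynomial in x
  pow <- 1                            # z^0
  for (k in seq_along(zco)) {
    out <- poly_add(out, zco[k] * pow)
    if (k < length(zco)) pow <- poly_mul(pow, lin)
  }
  out
}

poly_add <- function(a, b) {
  n <- max(length(a), length(b))
  c(a, rep(0, n - length(a))) + c(b, rep(0, n - length(b)))
}

poly_mul <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a))
    out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
  out
}

#' Fit the population mean growth curve by polynomial least squares
#'
#' Fits `height = P(age)` with `P` a degree-`degree` polynomial minimising
#' the sum of squared residuals over the reference grid, and returns the
#' fitted mean growth curve.
#'
#' @param table A [reference_table()].
#' @param degree Polynomial degree (>= 1).  Degrees 4--6 reproduce the
#'   smooth sigmoid-like shape of childhood mean growth on typical reference
#'   grids; the default is 5.
#' @return An object of class `mean_growth_curve` with fields `sex`,
#'   `coefficients` (raw-age basis, highest power first), `degree`,
#'   `age_min`, `age_max` and `fit_rmse` (cm).
#' @details Ages are internally centred and scaled to `[-1, 1]` before the
#'   power design matrix is built (a raw Vandermonde over ages 0--18 at
#'   degree 5 is ill-conditioned) and the least-squares problem is solved by
#'   QR decomposition; the coefficients are then mapped back to the raw-age
#'   basis.  The returned solution agrees with the explicit normal-equation
#'   form \eqn{A = (X^T X)^{-1} X^T y} up to numerical tolerance.
#' @export
#' @examples
#' ref <- reference_table(0:3, c(50, 75, 87, 96), "male")
#' fit_mean_curve(ref, degree = 2)
fit_mean_curve <- function(table, degree = 5L) {
  if (!inherits(table, "reference_table"))
    stopf("`table` must be a reference_table")
  check_number(degree, "degree", lower = 1)
  degree <- as.integer(degree)
  k <- length(table$ages)
  if (k < degree + 1L)
    stopf("degree-%d fit needs at least %d points, table has %d",
          degree, degree + 1L, k)
  ctr <- mean(range(table$ages))
  scl <- diff(range(table$ages)) / 2
  z <- (table$ages - ctr) / scl
  X <- outer(z, 0:degree, `^`)
  qrx <- qr(X)
  if (qrx$rank < degree + 1L)
    stopf("rank-deficient design: fewer than %d distinct ages", degree + 1L)
  zco <- qr.coef(qrx, table$heights)          # lowest power first, z basis
  fitted <- drop(X %*% zco)
  sse <- sum((fitted - table$heights)^2)
  raw <- rebase_poly(zco, ctr, scl)           # lowest power first, raw basis
  structure(list(sex = table$sex,
                 coefficients = rev(raw),     # highest power first
                 degree = degree,
                 age_min = min(table$ages),
                 age_max = max(table$ages),
                 fit_rmse = sqrt(sse / k),
                 sse = sse),
            class = "mean_growth_curve")
}

#' Construct a mean growth curve from known coefficients
#'
#' Mostly useful in examples and tests where the polynomial is known
#' exactly.
#'
#' @param coefficients Numeric vector, highest power first.
#' @param sex `"male"` or `"female"`.
#' @param age_min,age_max Fit domain in years.
#' @param fit_rmse Residual RMSE of the fit in cm (0 for an exact curve).
#' @return A `mean_growth_curve` object.
#' @export
mean_growth_curve <- function(coefficients, sex = "male",
                              age_min = 0, age_max = 18, fit_rmse = 0) {
  sex <- check_sex(sex)
  if (!is.numeric(coefficients) || length(coefficients) < 2L)
    stopf("`coefficients` must be numeric of length degree+1 >= 2")
  if (age_min >= age_max) stopf("age_min must be < age_max")
  if (fit_rmse < 0) stopf("fit_rmse must be >= 0")
  structure(list(sex = sex, coefficients = as.numeric(coefficients),
                 degree = length(coefficients) - 1L,
                 age_min = age_min, age_max = age_max,
                 fit_rmse = fit_rmse, sse = NA_real_),
            class = "mean_growth_curve")
}

#' @export
print.mean_growth_curve <- function(x, ...) {
  cat(sprintf("Mean growth curve (%s): degree %d on ages [%g, %g], fit RMSE %.3f cm\n",
              x$sex, x$degree, x$age_min, x$age_max, x$fit_rmse))
  cat("  coefficients (highest power first):",
      paste(signif(x$coefficients, 6), collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate a mean growth curve at given ages
#'
#' Horner evaluation of the fitted polynomial.  Ages above `age_max` are
#' clamped to `age_max` — mean height plateaus at adulthood, consistent with
#' anchoring the amplitude shift at the age-18 mean height.  Ages below
#' `age_min` are an error rather than an extrapolation.
#'
#' @param curve A `mean_growth_curve`.
#' @param age Numeric vector of ages in years.
#' @return Heights in cm, same length as `age`.
#' @export
#' @examples
#' cv <- mean_growth_curve(c(2, 3, 1), age_min = 0, age_max = 18)
#' eval_curve(cv, 2)  # 2*4 + 3*2 + 1 = 15
eval_curve <- function(curve, age) {
  if (!inherits(curve, "mean_growth_curve"))
    stopf("`curve` must be a mean_growth_curve")
  if (!is.numeric(age) || anyNA(age) || any(!is.finite(age)))
    stopf("`age` must be finite numeric")
  if (any(age < curve$age_min - 1e-12))
    stopf("age %g is below the curve domain (age_min = %g); refusing to extrapolate",
          min(age), curve$age_min)
  x <- pmin(age, curve$age_max)
  co <- curve$coefficients                    # highest first
  acc <- rep(co[1], length(x))
  for (j in seq_along(co)[-1]) acc <- acc * x + co[j]
  acc
}

#' @rdname eval_curve
#' @param object A `mean_growth_curve`.
#' @param ... Unused.
#' @export
predict.mean_growth_curve <- function(object, age, ...) eval_curve(object, age)

#' Serialize / read a mean growth curve as JSON
#'
#' @param curve A `mean_growth_curve`.
#' @param path Output (input) file path.
#' @return `write_mean_curve` returns `path` invisibly; `read_mean_curve`
#'   returns the curve.
#' @export
write_mean_curve <- function(curve, path) {
  if (!inherits(curve, "mean_growth_curve"))
    stopf("`curve` must be a mean_growth_curve")
  jsonlite::write_json(
    list(sex = curve$sex, degree = curve$degree,
         coefficients = curve$coefficients,
         age_min = curve$age_min, age_max = curve$age_max,
         fit_rmse = curve$fit_rmse),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mean_curve
#' @export
read_mean_curve <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  mean_growth_curve(obj$coefficients, sex = obj$sex,
                    age_min = obj$age_min, age_max = obj$age_max,
                    fit_rmse = obj$fit_rmse)
}
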