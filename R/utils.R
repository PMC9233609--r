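# Internal helpers shared across modules.

stopf <- function(...) stop(sprintf(...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         open_lower = FALSE, open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("`%s` must be a single finite number", name)
  lo_ok <- if (open_lower) x > lower else x >= lower
  hi_ok <- if (open_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stopf("`%s` = %g is outside the allowed range %s%g, %g%s", name, x,
          if (open_lower) "(" else "[", lower, upper,
          if (open_upper) ")" else "]")
  invisible(x)
}

check_sex <- function(sex) {
  if (!is.character(sex) || length(sex) != 1L ||
      !sex %in% c("male", "female"))
    stopf('`sex` must be "male" or "female"')
  sex
}

# Map common cohort encodings (M/F) onto the canonical labels.
normalize_sex <- function(x) {
  out <- tolower(as.character(x))
  out[out %in% c("m", "male", "boy")] <- "male"
  out[out %in% c("f", "female", "girl")] <- "female"
  bad <- !out %in% c("male", "female")
  if (any(bad))
    stopf("unrecognised sex code(s): %s",
          paste(unique(x[bad]), collapse = ", "))
  out
}

# Linear interpolation on a strictly increasing grid; errors outside range.
interp_grid <- function(xgrid, ygrid, x, what = "value") {
  if (any(x < min(xgrid) - 1e-12) || any(x > max(xgrid) + 1e-12))
    stopf("%s %s outside the table range [%g, %g]", what,
          paste(signif(x[x < min(xgrid) | x > max(xgrid)], 6), collapse = ", "),
          min(xgrid), max(xgrid))
  stats::approx(xgrid, ygrid, xout = pmin(pmax(x, min(xgrid)), max(xgrid)),
                method = "linear", ties = "ordered")$y
}

# Round half away from zero (display convention for deviation tables).
round_half_away <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards so library calls do not disturb user simulations.
with_local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

read_strict_csv <- function(path, required, what) {
  if (!file.exists(path)) stopf("%s file not found: %s", what, path)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stopf("malformed %s CSV (%s): %s",
                                           what, path, conditionMessage(e)))
  missing <- setdiff(required, names(df))
  if (length(missing))
    stopf("%s CSV %s lacks required column(s): %s", what, path,
          paste(missing, collapse = ", "))
  df
}
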