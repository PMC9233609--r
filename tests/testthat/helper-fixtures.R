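# Shared fixtures and independent oracles, all built in code.

extdata <- function(f) system.file("extdata", f, package = "staturecast")

bundled_curve <- local({
  cache <- list()
  function(sex = "male", degree = 5) {
    key <- paste(sex, degree)
    if (is.null(cache[[key]])) {
      ref <- load_reference_table(
        extdata(sprintf("reference_0sd_%s_synthetic.csv", sex)), sex)
      cache[[key]] <<- fit_mean_curve(ref, degree = degree)
    }
    cache[[key]]
  }
})

bundled_bmi <- function(sex = "male") {
  load_bmi_table(extdata("standard_bmi_synthetic.csv"), sex)
}

write_temp_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# Independent least-squares oracle: explicit normal equations
# A = (X^T X)^{-1} X^T y on the raw power basis (adequate at low degree).
normal_equation_fit <- function(ages, heights, degree) {
  X <- outer(ages, degree:0, `^`)
  solve(crossprod(X), crossprod(X, heights))[, 1]
}

# Central finite differences of a scalar function of a vector.
fd_gradient <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, 0)
}

# Dense grid search over the registration objective: the reference the
# bounded solver must never do worse than (alpha step 0.01 on [0.6, 1.4],
# beta step 0.01 on [-3, 3]).
grid_search_objective <- function(observations, adult_height, gamma, base,
                                  adult_age = 18) {
  g <- expand.grid(alpha = seq(0.6, 1.4, by = 0.01),
                   beta = seq(-3, 3, by = 0.01))
  min(registration_objective(g$alpha, g$beta, gamma, observations,
                             adult_height, base, adult_age))
}

# Sort-based type-7 quantile oracle (linear interpolation between order
# statistics), written independently of stats::quantile.
quantile7_oracle <- function(x, p) {
  s <- sort(x); n <- length(s)
  h <- (n - 1) * p
  lo <- floor(h) + 1
  hi <- pmin(lo + 1, n)
  s[lo] + (h - floor(h)) * (s[hi] - s[lo])
}
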