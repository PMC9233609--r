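#' Amplitude shift from predicted adult height
#'
#' The vertical (amplitude) shift of a child's growth curve relative to the
#' population mean curve: `gamma = H_final - f(adult_age)`.  Shorter
#' children have smaller (possibly negative) `gamma`.
#'
#' @param adult_height Predicted or verified adult height in cm.
#' @param base A [mean_growth_curve()].
#' @param adult_age Age at which adult height is anchored (default 18;
#'   must not exceed the base curve's domain handling — values above
#'   `age_max` are clamped by [eval_curve()]).
#' @return The amplitude shift in cm.
#' @export
#' @examples
#' cv <- mean_growth_curve(c(1, 154), age_min = 3, age_max = 18)  # f(18)=172
#' gamma_from_adult_height(175, cv)  # 3
gamma_from_adult_height <- function(adult_height, base, adult_age = 18) {
  check_number(adult_height, "adult_height", 40, 250)
  adult_height - eval_curve(base, adult_age)
}

# Clamped evaluation of the base curve at transformed ages plus a smooth
# quadratic penalty below the domain, keeping the search objective
# continuous instead of failing hard.
eval_with_penalty <- function(base, t, penalty_weight = 100) {
  below <- pmax(base$age_min - t, 0)
  h <- eval_curve(base, pmax(t, base$age_min))
  list(h = h, penalty = penalty_weight * sum(below^2))
}

#' Sum-of-squares objective of the personal-curve registration
#'
#' For given tempo `alpha` and phase `beta` (amplitude `gamma` held fixed),
#' the sum over all anchors -- the observed `(age, height)` pairs plus the
#' adult anchor `(adult_age, adult_height)` -- of
#' `(f(alpha * age + beta) + gamma - height)^2`, with the base curve
#' clamped above its domain and a smooth quadratic penalty for transformed
#' ages below it.  Vectorised over `(alpha, beta)` so a dense grid can be
#' scanned cheaply.
#'
#' @param alpha,beta Numeric vectors (recycled to common length).
#' @param gamma Fixed amplitude shift in cm.
#' @param observations Data frame with columns `age`, `height`.
#' @param adult_height Adult-height anchor in cm.
#' @param base A [mean_growth_curve()].
#' @param adult_age Adult anchor age (default 18).
#' @return Numeric vector of objective values (cm^2).
#' @export
registration_objective <- function(alpha, beta, gamma, observations,
                                   adult_height, base, adult_age = 18) {
  k <- max(length(alpha), length(beta))
  alpha <- rep_len(alpha, k); beta <- rep_len(beta, k)
  ages <- c(observations$age, adult_age)
  hts <- c(observations$height, adult_height)
  tot <- numeric(k)
  for (j in seq_along(ages)) {
    t <- alpha * ages[j] + beta
    below <- pmax(base$age_min - t, 0)
    h <- eval_curve(base, pmax(t, base$age_min))
    tot <- tot + (h + gamma - hts[j])^2 + 100 * below^2
  }
  tot
}

#' Fit a child's personal growth curve
#'
#' Registers the population mean curve to one child:
#' `H(x) = f(alpha * x + beta) + gamma`, where `alpha` is the growth tempo
#' (`alpha < 1` for a fast, early-ending pubertal course), `beta` the phase
#' shift in years (positive for early developers) and `gamma` the amplitude
#' shift in cm.
#'
#' By default `gamma` is fixed first from the adult anchor
#' (`gamma = adult_height - f(adult_age)`), then `(alpha, beta)` minimise
#' the residual sum of squares over all anchors by bounded nonlinear least
#' squares -- the two-anchor case is the classical contradictory 2-equation
#' system in 2 unknowns, and additional historical measurements enter the
#' same residual sum.  With `joint = TRUE` all three parameters are
#' re-estimated jointly (`gamma` is profiled out in closed form), which is
#' the mode that recovers a generating `(alpha, beta, gamma)` triple
#' exactly from noiseless data.
#'
#' The optimiser is L-BFGS-B within `alpha` in `[0.5, 1.5]`,
#' `beta` in `[-4, 4]`, polished from `(1, 0)` and from the best cells of a
#' coarse multistart grid, so the reported objective is no worse than a
#' dense grid search.
#'
#' @param observations Data frame with columns `age`, `height` (>= 1 row);
#'   observation ages must lie below `adult_age`.
#' @param adult_height Adult-height anchor in cm (typically the MLP
#'   prediction, or the verified value).
#' @param base A [mean_growth_curve()].
#' @param adult_age Adult anchor age (default 18).
#' @param joint Re-estimate `gamma` jointly with `(alpha, beta)`?
#' @param bounds List with elements `alpha` and `beta`, each a length-2
#'   range.
#' @return An object of class `personal_curve` with fields `alpha`, `beta`,
#'   `gamma`, `base`, `objective` (residual sum of squares at the optimum)
#'   and `adult_age`.
#' @export
fit_personal_curve <- function(observations, adult_height, base,
                               adult_age = 18, joint = FALSE,
                               bounds = list(alpha = c(0.5, 1.5),
                                             beta = c(-4, 4))) {
  if (!inherits(base, "mean_growth_curve"))
    stopf("`base` must be a mean_growth_curve")
  observations <- as.data.frame(observations)
  if (!all(c("age", "height") %in% names(observations)))
    stopf("`observations` needs columns age and height")
  if (nrow(observations) < 1L) stopf("need at least one observation anchor")
  if (any(observations$age >= adult_age))
    stopf("observation ages must be below the adult age %g", adult_age)
  if (any(observations$height <= 0)) stopf("observation heights must be positive")
  check_number(adult_height, "adult_height", 40, 250)

  gamma0 <- gamma_from_adult_height(adult_height, base, adult_age)
  ages <- c(observations$age, adult_age)
  hts <- c(observations$height, adult_height)

  obj_fixed <- function(par) {
    registration_objective(par[1], par[2], gamma0, observations,
                           adult_height, base, adult_age)
  }
  # Joint mode: profile gamma out in closed form (clamp/penalty ignores
  # gamma, so the optimal gamma given (alpha, beta) is the mean residual).
  gamma_of <- function(par) {
    t <- par[1] * ages + par[2]
    mean(hts - eval_curve(base, pmax(t, base$age_min)))
  }
  obj_joint <- function(par) {
    registration_objective(par[1], par[2], gamma_of(par), observations,
                           adult_height, base, adult_age)
  }
  obj <- if (joint) obj_joint else obj_fixed

  lower <- c(bounds$alpha[1], bounds$beta[1])
  upper <- c(bounds$alpha[2], bounds$beta[2])
  ga <- seq(lower[1], upper[1], length.out = 41)
  gb <- seq(lower[2], upper[2], length.out = 33)
  grid <- expand.grid(alpha = ga, beta = gb)
  gv <- if (joint) apply(grid, 1, obj_joint)
        else registration_objective(grid$alpha, grid$beta, gamma0,
                                    observations, adult_height, base,
                                    adult_age)
  # greedy diverse multistart: the objective can have several basins, and
  # the best coarse cells tend to cluster inside one of them — accept each
  # next-best cell only if it is well separated from already-chosen starts
  ord <- order(gv)
  chosen <- matrix(numeric(0), ncol = 2)
  for (i in ord) {
    cand <- c(grid$alpha[i], grid$beta[i])
    if (nrow(chosen) == 0 ||
        all(abs(chosen[, 1] - cand[1]) > 0.06 |
            abs(chosen[, 2] - cand[2]) > 0.5))
      chosen <- rbind(chosen, cand)
    if (nrow(chosen) >= 6) break
  }
  starts <- rbind(c(1, 0), chosen)

  fits <- list()
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(pmin(pmax(starts[s, ], lower), upper), obj,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(factr = 1e2, maxit = 1000)),
      error = function(e) NULL)
    if (is.null(fit)) next
    # the clamp boundary introduces gradient kinks; a derivative-free
    # polish guards against premature L-BFGS-B termination there
    nm <- tryCatch(stats::optim(fit$par, obj, method = "Nelder-Mead",
                                control = list(reltol = 1e-12,
                                               maxit = 400)),
                   error = function(e) NULL)
    if (!is.null(nm)) {
      par <- pmin(pmax(nm$par, lower), upper)
      val <- obj(par)
      if (val < fit$value) fit <- list(par = par, value = val)
    }
    fits[[length(fits) + 1L]] <- fit
  }
  if (length(fits) == 0L)
    stopf("personal-curve solver failed to converge from any start")
  vals <- vapply(fits, `[[`, 0, "value")
  # A single observation plus a plateau-satisfied adult anchor leaves a flat
  # ridge of equal-objective solutions; among (near-)ties prefer the one
  # closest to the identity transformation (1, 0).
  tied <- which(vals <= min(vals) + 1e-9)
  dist <- vapply(fits[tied], function(f)
    (f$par[1] - 1)^2 + (f$par[2] / 4)^2, 0)
  best <- fits[[tied[which.min(dist)]]]

  par <- unname(best$par)
  gamma <- unname(if (joint) gamma_of(par) else gamma0)
  structure(list(alpha = par[1], beta = par[2], gamma = gamma,
                 base = base, objective = best$value,
                 adult_age = adult_age, joint = joint,
                 n_observations = nrow(observations)),
            class = "personal_curve")
}

#' @export
print.personal_curve <- function(x, ...) {
  cat(sprintf(
    "Personal growth curve: alpha %.4f, beta %+.4f y, gamma %+.2f cm (objective %.4g, %d obs%s)\n",
    x$alpha, x$beta, x$gamma, x$objective, x$n_observations,
    if (x$joint) ", joint fit" else ""))
  invisible(x)
}

#' Predict stage height from a personal curve
#'
#' Evaluates `f(alpha * age + beta) + gamma` at the target age(s).
#' Transformed ages above the base domain are clamped (adult plateau);
#' below it they are an error.
#'
#' @param curve A `personal_curve`.
#' @param target_age Age(s) in years.
#' @return Predicted height(s) in cm.
#' @export
predict_stage_height <- function(curve, target_age) {
  if (!inherits(curve, "personal_curve"))
    stopf("`curve` must be a personal_curve")
  eval_curve(curve$base, curve$alpha * target_age + curve$beta) + curve$gamma
}

#' @rdname predict_stage_height
#' @param object A `personal_curve`.
#' @param ... Unused.
#' @export
predict.personal_curve <- function(object, target_age, ...) {
  predict_stage_height(object, target_age)
}
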