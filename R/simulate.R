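#' Configuration of the longitudinal cohort simulator
#'
#' The simulator draws, for each child, a tempo/phase/amplitude triple
#' `(alpha, beta, gamma)` around the population mean curve, and emits a
#' small number of visits with noisy height, a bone age tied to the child's
#' developmental age, and a weight derived from a per-subject BMI
#' trajectory.  All distributional choices are synthetic (the study data
#' behind the method are private) and are documented in the package
#' vignette.
#'
#' @param n_subjects Number of children.
#' @param sex `"male"` or `"female"`.
#' @param seed Integer seed; the cohort is a pure function of
#'   `(config, base curve)`.
#' @param alpha_sd SD of `log(alpha)` (lognormal around 1; default 0.05).
#' @param beta_sd SD of the phase shift in years (default 0.8).
#' @param gamma_sd SD of the amplitude shift in cm (default 4.0).
#' @param noise_sd Height measurement noise in cm (default 0.5).
#' @param bone_age_noise_sd Bone-age assessment noise in years
#'   (default 0.25).
#' @param bone_age_offset_scale Years of bone-age advancement per year of
#'   developmental advancement (default 1: bone age reads the child's
#'   developmental age `alpha * age + beta` directly).
#' @param visit_ages Either a numeric vector of visit ages used for every
#'   subject, or `NULL` (default) to draw a first visit age uniformly on
#'   `[8, 13]` with follow-ups spaced `visit_gap` years apart.
#' @param n_visits Visits per subject when `visit_ages` is `NULL`
#'   (default 2).
#' @param visit_gap Spacing between visits in years (default 1).
#' @param bmi_table A [standard_bmi_table()] used as the BMI-for-age
#'   backbone, or `NULL` to use a smooth built-in median curve.
#' @param bmi_sd SD of the per-subject BMI offset in kg/m^2 (default 1.5).
#' @param bmi_visit_sd Visit-level BMI jitter (default 0.3).
#' @param bmi_beta_cor Correlation between the BMI offset and the phase
#'   `beta` (default 0.4): heavier children tend to mature earlier, which
#'   is the mechanism that makes the BMI features informative.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_subjects, sex = "male", seed = 1L,
                              alpha_sd = 0.05, beta_sd = 0.8,
                              gamma_sd = 4.0, noise_sd = 0.5,
                              bone_age_noise_sd = 0.25,
                              bone_age_offset_scale = 1.0,
                              visit_ages = NULL, n_visits = 2L,
                              visit_gap = 1.0,
                              bmi_table = NULL, bmi_sd = 1.5,
                              bmi_visit_sd = 0.3, bmi_beta_cor = 0.4) {
  sex <- check_sex(sex)
  check_number(n_subjects, "n_subjects", lower = 1)
  for (nm in c("alpha_sd", "beta_sd", "gamma_sd", "noise_sd",
               "bone_age_noise_sd", "bmi_sd", "bmi_visit_sd"))
    check_number(get(nm), nm, lower = 0)
  check_number(bmi_beta_cor, "bmi_beta_cor", -1, 1)
  check_number(n_visits, "n_visits", lower = 1)
  structure(list(n_subjects = as.integer(n_subjects), sex = sex,
                 seed = as.integer(seed),
                 alpha_sd = alpha_sd, beta_sd = beta_sd, gamma_sd = gamma_sd,
                 noise_sd = noise_sd,
                 bone_age_noise_sd = bone_age_noise_sd,
                 bone_age_offset_scale = bone_age_offset_scale,
                 visit_ages = visit_ages, n_visits = as.integer(n_visits),
                 visit_gap = visit_gap,
                 bmi_table = bmi_table, bmi_sd = bmi_sd,
                 bmi_visit_sd = bmi_visit_sd, bmi_beta_cor = bmi_beta_cor),
            class = "simulation_config")
}

# Smooth fallback median BMI-for-age (kg/m^2), loosely WHO-shaped.
default_bmi_median <- function(age) {
  15.2 + 0.28 * pmax(age - 8, 0) + 0.02 * pmax(age - 8, 0)^2
}

sim_bmi_median <- function(config, age) {
  if (is.null(config$bmi_table)) default_bmi_median(age)
  else standard_bmi_at(config$bmi_table, age)
}

#' Simulate a longitudinal growth cohort
#'
#' Each child's true growth curve is
#' `H(x) = f(alpha * x + beta) + gamma` around the supplied mean curve
#' (transformed ages above the domain are clamped at the adult plateau).
#' Observed visit heights add `N(0, noise_sd)` measurement error; the true
#' adult height is the personal curve at age 18, noise-free.  Bone age is
#' the child's developmental age `alpha * age + beta` (scaled by
#' `bone_age_offset_scale` relative to chronological age) plus assessment
#' noise, so early developers (positive `beta`) show advanced bone age.
#' Weight is reconstructed from a per-subject BMI trajectory so the BMI
#' features carry the maturation signal.
#'
#' @param config A [simulation_config()].
#' @param base A [mean_growth_curve()] valid on all sampled transformed
#'   ages.
#' @return An object of class `synthetic_cohort`: a list with `subjects`
#'   (per-child truths and visit records) and `config`; use
#'   [cohort_frame()] and [truth_frame()] for flat data frames.
#' @export
simulate_cohort <- function(config, base) {
  if (!inherits(config, "simulation_config"))
    stopf("`config` must be a simulation_config")
  if (!inherits(base, "mean_growth_curve"))
    stopf("`base` must be a mean_growth_curve")
  n <- config$n_subjects
  with_local_seed(config$seed, {
    alpha <- exp(stats::rnorm(n, 0, config$alpha_sd))
    z_bmi <- stats::rnorm(n)
    z_beta <- stats::rnorm(n)
    rho <- config$bmi_beta_cor
    beta <- config$beta_sd * (rho * z_bmi + sqrt(1 - rho^2) * z_beta)
    gamma <- stats::rnorm(n, 0, config$gamma_sd)
    bmi_offset <- config$bmi_sd * z_bmi

    subjects <- vector("list", n)
    for (i in seq_len(n)) {
      ages <- if (!is.null(config$visit_ages)) as.numeric(config$visit_ages)
              else stats::runif(1, 8, 13) +
                   config$visit_gap * (seq_len(config$n_visits) - 1L)
      t <- alpha[i] * ages + beta[i]
      if (any(t < base$age_min))
        stopf("subject %d: transformed age %.2f below the curve domain %.2f; adjust the config",
              i, min(t), base$age_min)
      h_true <- eval_curve(base, t) + gamma[i]
      h_obs <- h_true + stats::rnorm(length(ages), 0, config$noise_sd)
      bone <- ages + config$bone_age_offset_scale *
        ((alpha[i] - 1) * ages + beta[i]) +
        stats::rnorm(length(ages), 0, config$bone_age_noise_sd)
      bmi <- sim_bmi_median(config, ages) + bmi_offset[i] +
        stats::rnorm(length(ages), 0, config$bmi_visit_sd)
      weight <- bmi * (h_obs / 100)^2
      adult <- eval_curve(base, 18 * alpha[i] + beta[i]) + gamma[i]
      subjects[[i]] <- list(
        subject_id = sprintf("%s%04d", toupper(substr(config$sex, 1, 1)), i),
        sex = config$sex, alpha = alpha[i], beta = beta[i], gamma = gamma[i],
        adult_height = adult,
        visits = data.frame(age = ages, bone_age = bone,
                            height_true = h_true, height = h_obs,
                            weight = weight))
    }
    structure(list(subjects = subjects, config = config, base = base),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  nv <- sum(vapply(x$subjects, function(s) nrow(s$visits), 1L))
  cat(sprintf("Synthetic cohort (%s): %d subjects, %d visit records, seed %d\n",
              x$config$sex, length(x$subjects), nv, x$config$seed))
  invisible(x)
}

#' Flat visit-level view of a synthetic cohort
#'
#' One row per visit, in the cohort CSV schema used across the package
#' (`subject_id, sex, age, bone_age, height, weight, adult_height`), plus a
#' `visit` index.
#'
#' @param cohort A `synthetic_cohort`.
#' @return A data frame.
#' @export
cohort_frame <- function(cohort) {
  if (!inherits(cohort, "synthetic_cohort"))
    stopf("`cohort` must be a synthetic_cohort")
  do.call(rbind, lapply(cohort$subjects, function(s) {
    data.frame(subject_id = s$subject_id, sex = s$sex,
               visit = seq_len(nrow(s$visits)),
               age = s$visits$age, bone_age = s$visits$bone_age,
               height = s$visits$height, weight = s$visits$weight,
               adult_height = s$adult_height)
  }))
}

#' Per-subject ground truth of a synthetic cohort
#'
#' @param cohort A `synthetic_cohort`.
#' @return A data frame with one row per subject: `subject_id, sex, alpha,
#'   beta, gamma, adult_height`.
#' @export
truth_frame <- function(cohort) {
  if (!inherits(cohort, "synthetic_cohort"))
    stopf("`cohort` must be a synthetic_cohort")
  do.call(rbind, lapply(cohort$subjects, function(s) {
    data.frame(subject_id = s$subject_id, sex = s$sex, alpha = s$alpha,
               beta = s$beta, gamma = s$gamma, adult_height = s$adult_height)
  }))
}

#' Export a synthetic cohort to CSV
#'
#' Writes the visit-level cohort CSV (features-module schema) and a
#' per-subject truth CSV.
#'
#' @param cohort A `synthetic_cohort`.
#' @param cohort_path,truth_path Output paths.
#' @return Invisibly, a character vector of the two paths.
#' @export
export_cohort <- function(cohort, cohort_path, truth_path) {
  if (length(cohort$subjects) == 0L) stopf("empty cohort")
  utils::write.csv(cohort_frame(cohort), cohort_path, row.names = FALSE)
  utils::write.csv(truth_frame(cohort), truth_path, row.names = FALSE)
  invisible(c(cohort_path, truth_path))
}

#' Irreducible adult-height error of the simulator
#'
#' A plug-in reference predictor that knows the generator's own structure
#' — the true mean curve and the bone-age link — but sees only the
#' observable fields: it reads the developmental age off the bone age and
#' predicts `adult = f(18) + height - f(bone_age)`.  Its mean absolute
#' error is the simulator's noise floor for adult-height prediction (the
#' residual error driven by measurement and bone-age assessment noise);
#' no model trained on the observables should be expected to beat it.
#'
#' @param cohort A `synthetic_cohort`.
#' @param visit Which visit to predict from (default 1).
#' @return A list with `mae` (cm) and the per-subject `errors`.
#' @export
adult_height_noise_floor <- function(cohort, visit = 1L) {
  base <- cohort$base
  frame <- cohort_frame(cohort)
  frame <- frame[frame$visit == visit, , drop = FALSE]
  devage <- pmax(frame$bone_age, base$age_min)
  pred <- eval_curve(base, 18) + frame$height - eval_curve(base, devage)
  err <- pred - frame$adult_height
  list(mae = mean(abs(err)), errors = err)
}
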