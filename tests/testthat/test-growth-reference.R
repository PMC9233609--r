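test_that("reference tables load, sort and validate", {
  path <- write_temp_csv(data.frame(age = c(8, 6, 7), height = c(127, 116, 122)))
  tab <- load_reference_table(path, "male")
  expect_s3_class(tab, "reference_table")
  expect_equal(tab$ages, c(6, 7, 8))
  expect_equal(tab$heights, c(116, 122, 127))

  dup <- write_temp_csv(data.frame(age = c(6, 7, 7), height = c(116, 122, 123)))
  expect_error(load_reference_table(dup, "male"), "strictly increasing")

  short <- write_temp_csv(data.frame(age = 6, height = 116))
  expect_error(load_reference_table(short, "male"), "at least 2")

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines(character(0), empty)
  expect_error(load_reference_table(empty, "male"))

  nocol <- write_temp_csv(data.frame(a = 1:3, b = 4:6))
  expect_error(load_reference_table(nocol, "female"), "required column")
  expect_error(load_reference_table("no/such/file.csv", "male"), "not found")
})

test_that("polynomial fits recover exact generating polynomials", {
  line <- fit_mean_curve(reference_table(1:3, c(1, 2, 3), "male"), degree = 1)
  expect_equal(line$coefficients, c(1, 0), tolerance = 1e-9)
  expect_lt(line$sse, 1e-16)

  ages <- 1:5
  tab <- reference_table(ages, 2 * ages^2 + 3 * ages + 1, "male")
  quad <- fit_mean_curve(tab, degree = 2)
  expect_equal(quad$coefficients, c(2, 3, 1), tolerance = 1e-8)
  expect_lt(quad$sse, 1e-8)
  expect_equal(eval_curve(quad, 2), 15, tolerance = 1e-9)

  # degree above the generating one still reproduces the data
  cubic <- fit_mean_curve(reference_table(ages, 2 * ages^2 + 3 * ages + 1, "male"),
                          degree = 3)
  expect_lt(cubic$sse, 1e-8)
})

test_that("degree-5 fit on a 19-point grid agrees with an independent QR oracle", {
  ages <- seq(2, 18, length.out = 19)
  set.seed(11)
  heights <- 80 + 6 * ages - 0.05 * ages^2 + 5 * sin(ages / 3) +
    rnorm(19, 0, 0.2)
  fit <- fit_mean_curve(reference_table(ages, heights, "male"), degree = 5)

  # independent path: orthogonal-polynomial regression via lm (QR inside)
  oracle <- lm(heights ~ poly(ages, 5))
  expect_equal(eval_curve(fit, ages), unname(fitted(oracle)),
               tolerance = 1e-6)
  expect_equal(sqrt(fit$sse), sqrt(sum(resid(oracle)^2)), tolerance = 1e-8)

  # explicit normal-equation oracle at a degree where it is well conditioned
  tab3 <- reference_table(ages, heights, "male")
  fit3 <- fit_mean_curve(tab3, degree = 3)
  expect_equal(fit3$coefficients,
               unname(normal_equation_fit(ages, heights, 3)),
               tolerance = 1e-6)
})

test_that("fit errors on rank deficiency and insufficient points", {
  tab <- reference_table(c(5, 6, 7), c(110, 116, 122), "male")
  expect_error(fit_mean_curve(tab, degree = 3), "at least 4 points")
  expect_error(fit_mean_curve(tab, degree = 0), "degree")
})

test_that("evaluation clamps above the domain and refuses below it", {
  cv <- mean_growth_curve(c(1, 0), age_min = 3, age_max = 18)
  expect_equal(eval_curve(cv, 7), 7)
  fit <- bundled_curve("male")
  expect_equal(eval_curve(fit, 25), eval_curve(fit, fit$age_max))
  expect_equal(predict(fit, 25), eval_curve(fit, 18))
  expect_error(eval_curve(fit, 2), "below the curve domain")
  expect_error(eval_curve(fit, NaN), "finite")
})

test_that("fit quality behaves like nested least squares", {
  ref <- load_reference_table(extdata("reference_0sd_male_synthetic.csv"), "male")
  rmse <- vapply(2:6, function(d) fit_mean_curve(ref, d)$fit_rmse, 0)
  expect_true(all(diff(rmse) <= 1e-10))  # non-increasing in degree

  # grid ages are reproduced with residuals consistent with fit_rmse: the
  # root-mean-square of the per-point residuals IS fit_rmse, and no single
  # residual can exceed sqrt(k) * fit_rmse
  for (sex in c("male", "female")) {
    tab <- load_reference_table(
      extdata(sprintf("reference_0sd_%s_synthetic.csv", sex)), sex)
    fit <- fit_mean_curve(tab, 5)
    resid <- eval_curve(fit, tab$ages) - tab$heights
    expect_equal(sqrt(mean(resid^2)), fit$fit_rmse, tolerance = 1e-9)
    expect_true(all(abs(resid) <=
                      sqrt(length(tab$ages)) * fit$fit_rmse + 1e-9))
    expect_lt(max(abs(resid)), 2)  # every grid age within a couple of cm
  }
})

test_that("fitting is invariant to shifting the age axis", {
  ref <- load_reference_table(extdata("reference_0sd_male_synthetic.csv"), "male")
  fit <- fit_mean_curve(ref, 5)
  shifted <- reference_table(ref$ages + 7, ref$heights, "male")
  fit_s <- fit_mean_curve(shifted, 5)
  expect_equal(eval_curve(fit_s, ref$ages + 7), eval_curve(fit, ref$ages),
               tolerance = 1e-6)
})

test_that("mean curves round-trip through JSON", {
  fit <- bundled_curve("female")
  path <- withr::local_tempfile(fileext = ".json")
  write_mean_curve(fit, path)
  back <- read_mean_curve(path)
  expect_equal(back$coefficients, fit$coefficients)
  expect_equal(back$sex, "female")
  ages <- seq(4, 18, by = 0.5)
  expect_equal(eval_curve(back, ages), eval_curve(fit, ages))
})
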