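test_that("the amplitude shift is adult height minus the age-18 mean height", {
  cv <- bundled_curve("male")
  f18 <- eval_curve(cv, 18)
  expect_equal(gamma_from_adult_height(f18, cv), 0)
  expect_equal(gamma_from_adult_height(f18 + 3, cv), 3)
  # short children carry a negative shift
  expect_equal(gamma_from_adult_height(f18 - 5, cv), -5)
})

test_that("identity anchors recover the identity transformation", {
  cv <- bundled_curve("male")
  ages <- c(9, 11, 13)
  obs <- data.frame(age = ages, height = eval_curve(cv, ages))
  pc <- fit_personal_curve(obs, eval_curve(cv, 18), cv)
  expect_equal(pc$alpha, 1, tolerance = 1e-4)
  expect_equal(pc$beta, 0, tolerance = 1e-4)
  expect_equal(pc$gamma, 0, tolerance = 1e-9)
  expect_lt(pc$objective, 1e-8)
})

test_that("a joint fit recovers a generating (alpha, beta, gamma) triple", {
  cv <- bundled_curve("male")
  for (tru in list(c(0.9, 0.8, 2.5), c(1.1, -1.0, -3.0))) {
    ages <- c(9.5, 11, 12.5)
    obs <- data.frame(age = ages,
                      height = eval_curve(cv, tru[1] * ages + tru[2]) + tru[3])
    hf <- eval_curve(cv, tru[1] * 18 + tru[2]) + tru[3]
    pc <- fit_personal_curve(obs, hf, cv, joint = TRUE)
    expect_equal(c(pc$alpha, pc$beta, pc$gamma), tru, tolerance = 1e-3)
    probe <- c(10, 12, 14)
    expect_equal(predict_stage_height(pc, probe),
                 eval_curve(cv, tru[1] * probe + tru[2]) + tru[3],
                 tolerance = 0.01)
  }
})

test_that("stage predictions follow the transformed-curve definition", {
  cv <- bundled_curve("male")
  pc <- structure(list(alpha = 1.08, beta = -0.6, gamma = 1.7, base = cv,
                       adult_age = 18), class = "personal_curve")
  a <- c(8, 10.5, 13)
  expect_equal(predict_stage_height(pc, a),
               eval_curve(cv, 1.08 * a - 0.6) + 1.7)
  # vertical shift: gamma + 2 moves every prediction by exactly 2 cm
  pc2 <- pc; pc2$gamma <- pc$gamma + 2
  expect_equal(predict_stage_height(pc2, a), predict_stage_height(pc, a) + 2)
  # identity curve reproduces the mean curve at grid ages
  id <- structure(list(alpha = 1, beta = 0, gamma = 0, base = cv),
                  class = "personal_curve")
  expect_equal(predict_stage_height(id, 12), eval_curve(cv, 12))
})

test_that("fitting is equivariant to a vertical shift of all anchors", {
  cv <- bundled_curve("female")
  obs <- data.frame(age = c(10, 11.5), height = c(141.3, 150.2))
  hf <- 161.8
  pc <- fit_personal_curve(obs, hf, cv)
  shift <- 2.5
  pc_s <- fit_personal_curve(
    data.frame(age = obs$age, height = obs$height + shift), hf + shift, cv)
  a <- c(12, 13, 15)
  expect_equal(predict_stage_height(pc_s, a),
               predict_stage_height(pc, a) + shift, tolerance = 1e-6)
})

test_that("personal curves preserve monotonicity of a non-decreasing base", {
  # base with strictly positive derivative on its whole domain
  cv <- mean_growth_curve(c(0.01, 0, 4, 70), sex = "male",
                          age_min = 3, age_max = 18)
  obs <- data.frame(age = c(9, 10.5),
                    height = eval_curve(cv, c(9, 10.5) * 0.95 + 0.4) + 2)
  pc <- fit_personal_curve(obs, eval_curve(cv, 17.5) + 2, cv)
  expect_gt(pc$alpha, 0)
  ages <- seq((cv$age_min - pc$beta) / pc$alpha + 0.01, 22, by = 0.1)
  h <- predict_stage_height(pc, ages)
  expect_true(all(diff(h) >= -1e-9))
})

test_that("the bounded solver never loses to a dense grid search", {
  cv <- bundled_curve("male")
  set.seed(31)
  for (rep in 1:8) {
    alpha <- exp(rnorm(1, 0, 0.05)); beta <- rnorm(1, 0, 0.8)
    gamma <- rnorm(1, 0, 4)
    ages <- sort(runif(2, 8.5, 12.5))
    obs <- data.frame(age = ages,
                      height = eval_curve(cv, alpha * ages + beta) + gamma +
                        rnorm(2, 0, 0.5))
    hf <- eval_curve(cv, min(18 * alpha + beta, 18)) + gamma
    pc <- fit_personal_curve(obs, hf, cv)
    oracle <- grid_search_objective(obs, hf, pc$gamma, cv)
    expect_lte(pc$objective, oracle + 1e-6)
  }
})

test_that("degenerate anchor sets are rejected", {
  cv <- bundled_curve("male")
  expect_error(fit_personal_curve(data.frame(age = 19, height = 170), 172, cv),
               "below the adult age")
  expect_error(fit_personal_curve(data.frame(x = 1), 172, cv), "columns")
  expect_error(fit_personal_curve(data.frame(age = 10, height = -5), 172, cv),
               "positive")
})
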