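# Small synthetic regression batch with a learnable structure.
make_batch <- function(n, seed = 1) {
  set.seed(seed)
  X <- cbind(bone_age = runif(n, 8, 14), age = runif(n, 8, 13),
             height = runif(n, 125, 165), weight = runif(n, 25, 60),
             bmi = runif(n, 14, 22), delta_bmi = rnorm(n, 0, 1.5))
  d <- 100 + 2 * X[, "bone_age"] + 0.35 * X[, "height"] - 0.5 * X[, "delta_bmi"]
  list(X = X, d = d)
}

test_that("training is deterministic given batch, config and seed", {
  b <- make_batch(40)
  cfg <- mlp_config(hidden_units = 20, iterations = 50,
                    learning_rate = 1e-3, seed = 9)
  m1 <- train_adult_height_mlp(b$X, b$d, cfg)
  m2 <- train_adult_height_mlp(b$X, b$d, cfg)
  expect_identical(m1$W1, m2$W1)
  expect_identical(m1$W2, m2$W2)
  expect_identical(m1$b2, m2$b2)
  expect_identical(predict_adult_height(m1, b$X),
                   predict_adult_height(m2, b$X))
})

test_that("gradient descent reduces the banded loss", {
  b <- make_batch(120)
  cfg0 <- mlp_config(hidden_units = 30, iterations = 1,
                     learning_rate = 1e-12, seed = 3)
  init_loss <- train_adult_height_mlp(b$X, b$d, cfg0)$final_loss
  cfg <- mlp_config(hidden_units = 30, iterations = 800,
                    learning_rate = 2e-3, seed = 3)
  m <- train_adult_height_mlp(b$X, b$d, cfg)
  expect_lt(m$final_loss, init_loss)
  expect_lt(m$final_loss, 1)  # the target is a simple linear map
})

test_that("training under band 0 follows an independent MSE reference exactly", {
  b <- make_batch(30, seed = 2)
  p <- ncol(b$X); h <- 10; lr <- 1e-3; iters <- 100; seed <- 21
  cfg <- mlp_config(hidden_units = h, iterations = iters,
                    learning_rate = lr, band = 0, seed = seed)
  m <- train_adult_height_mlp(b$X, b$d, cfg)

  # independent full-batch MSE gradient descent with the same He-uniform
  # init (same seeded draw order: W1 then W2) and z-scored inputs
  ctr <- colMeans(b$X); scl <- apply(b$X, 2, sd)
  X <- sweep(sweep(b$X, 2, ctr), 2, scl, `/`)
  set.seed(seed)
  W1 <- matrix(runif(p * h, -1, 1) * sqrt(6 / p), p, h)
  W2 <- matrix(runif(h, -1, 1) * sqrt(6 / h), h, 1)
  b1 <- numeric(h); b2 <- mean(b$d); n <- nrow(X)
  for (it in 1:iters) {
    Z1 <- sweep(X %*% W1, 2, b1, `+`); A1 <- pmax(Z1, 0)
    r <- drop(A1 %*% W2) + b2 - b$d
    g <- 2 * r / n
    gW2 <- crossprod(A1, g); gb2 <- sum(g)
    dA1 <- tcrossprod(g, W2) * (Z1 > 0)
    gW1 <- crossprod(X, dA1); gb1 <- colSums(dA1)
    W1 <- W1 - lr * gW1; b1 <- b1 - lr * gb1
    W2 <- W2 - lr * gW2; b2 <- b2 - lr * gb2
  }
  expect_equal(m$W1, W1, tolerance = 1e-6)
  expect_equal(m$b2, b2, tolerance = 1e-6)
  ref_loss <- mean((drop(pmax(sweep(X %*% W1, 2, b1, `+`), 0) %*% W2) + b2 -
                      b$d)^2)
  expect_equal(m$final_loss, ref_loss, tolerance = 1e-6)
})

test_that("prediction is a pure forward pass with stored scaling", {
  b <- make_batch(25)
  cfg <- mlp_config(hidden_units = 15, iterations = 30,
                    learning_rate = 1e-3, seed = 5)
  m <- train_adult_height_mlp(b$X, b$d, cfg)
  expect_identical(predict_adult_height(m, b$X[1, ]),
                   predict_adult_height(m, b$X[1, ]))

  # degenerate network: zero weights leave only the output bias
  z <- m
  z$W1[] <- 0; z$W2[] <- 0; z$b1[] <- 0; z$b2 <- 170
  expect_equal(predict_adult_height(z, b$X), rep(170, nrow(b$X)))

  expect_error(predict_adult_height(m, c(1, 2, 3)), "dimension")
  expect_error(predict_adult_height(m, b$X * NA), "non-finite")
})

test_that("an overfit-capable run drives training residuals near the band", {
  b <- make_batch(8, seed = 7)
  cfg <- mlp_config(hidden_units = 40, iterations = 4000,
                    learning_rate = 5e-3, seed = 7)
  m <- train_adult_height_mlp(b$X, b$d, cfg)
  resid <- abs(predict_adult_height(m, b$X) - b$d)
  expect_lt(max(resid), 0.5 + 0.5)  # band + tolerance
})

test_that("the forward pass is equivariant to feature permutation", {
  b <- make_batch(20)
  cfg <- mlp_config(hidden_units = 12, iterations = 40,
                    learning_rate = 1e-3, seed = 2)
  m <- train_adult_height_mlp(b$X, b$d, cfg)
  perm <- c(3, 1, 6, 2, 5, 4)
  mp <- m
  mp$W1 <- m$W1[perm, , drop = FALSE]
  mp$center <- m$center[perm]; mp$scale <- m$scale[perm]
  expect_equal(predict_adult_height(mp, b$X[, perm]),
               predict_adult_height(m, b$X))
})

test_that("train/validation splits are exact, seeded partitions", {
  df <- data.frame(id = seq_len(615))
  s <- split_train_validation(df, ratio = 0.75, seed = 42)
  expect_equal(nrow(s$train), 462)
  expect_equal(nrow(s$validation), 153)
  expect_setequal(c(s$train$id, s$validation$id), df$id)
  expect_length(intersect(s$train$id, s$validation$id), 0)

  s2 <- split_train_validation(df, ratio = 0.75, seed = 42)
  expect_identical(s$validation$id, s2$validation$id)
  s3 <- split_train_validation(df, ratio = 0.75, seed = 43)
  expect_false(identical(s$validation$id, s3$validation$id))

  tiny <- split_train_validation(data.frame(id = 1:4), ratio = 0.75, seed = 1)
  expect_equal(nrow(tiny$validation), 1)
  expect_error(split_train_validation(df[0, , drop = FALSE], 0.75, 1),
               "at least 2")
  expect_error(split_train_validation(df, ratio = 1.2, seed = 1), "ratio")
})

test_that("models round-trip through JSON with identical predictions", {
  b <- make_batch(30)
  cfg <- mlp_config(sex = "female", hidden_units = 8, iterations = 25,
                    learning_rate = 1e-3, seed = 13)
  m <- train_adult_height_mlp(b$X, b$d, cfg)
  path <- withr::local_tempfile(fileext = ".json")
  write_mlp_model(m, path)
  back <- read_mlp_model(path)
  expect_equal(back$sex, "female")
  expect_equal(back$config$iterations, 25L)
  expect_equal(predict_adult_height(back, b$X), predict_adult_height(m, b$X))
})
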