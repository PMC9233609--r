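#' Training configuration for the adult-height network
#'
#' Collects the hyper-parameters of the per-sex multilayer perceptron
#' (6 inputs, one ReLU hidden layer, one linear output) trained by
#' full-batch gradient descent under the banded squared loss.
#'
#' @param sex `"male"` or `"female"`; sets the default iteration count
#'   (46000 for the male model, 48500 for the female model).
#' @param hidden_units Hidden-layer width (default 100).
#' @param learning_rate Constant step size (default 5e-5, tuned for the
#'   default iteration counts).  For reduced-cost runs, scale the rate
#'   inversely with the iteration count so the product
#'   `learning_rate * iterations` is preserved (see the package vignette).
#' @param iterations Number of full-batch gradient steps.
#' @param band Tolerance half-width of the loss in cm (default 0.5).
#' @param momentum Optional classical momentum coefficient in `[0, 1)`;
#'   0 (off) by default — plain gradient descent is the reference
#'   behaviour.
#' @param standardize_inputs Z-score each feature using training-set
#'   statistics stored in the model (default `TRUE`; raw cm/kg scales at
#'   this learning rate would stall).
#' @param seed Integer seed for the weight initialisation.
#' @return A list of class `mlp_config`.
#' @export
mlp_config <- function(sex = "male", hidden_units = 100L,
                       learning_rate = 5e-5,
                       iterations = if (sex == "female") 48500L else 46000L,
                       band = 0.5, momentum = 0,
                       standardize_inputs = TRUE, seed = 1L) {
  sex <- check_sex(sex)
  check_number(hidden_units, "hidden_units", lower = 1)
  check_number(learning_rate, "learning_rate", lower = 0, open_lower = TRUE)
  check_number(iterations, "iterations", lower = 1)
  check_number(band, "band", lower = 0)
  check_number(momentum, "momentum", lower = 0, upper = 1, open_upper = TRUE)
  structure(list(sex = sex, hidden_units = as.integer(hidden_units),
                 activation = "relu",
                 learning_rate = learning_rate,
                 iterations = as.integer(iterations), band = band,
                 momentum = momentum,
                 standardize_inputs = isTRUE(standardize_inputs),
                 seed = as.integer(seed)),
            class = "mlp_config")
}

# He-uniform initialisation: U(-sqrt(6/fan_in), +sqrt(6/fan_in)).
he_uniform <- function(nr, nc) {
  matrix(stats::runif(nr * nc, -1, 1) * sqrt(6 / nr), nr, nc)
}

#' Train the per-sex adult-height network
#'
#' Full-batch gradient descent on the banded squared loss: every iteration
#' uses the whole training set (the cohorts are small, so full batches
#' maximise sample coverage per step).  Training is deterministic given
#' `(features, targets, config)`.
#'
#' The output bias is initialised at the mean training target and the
#' remaining weights He-uniform from the seeded RNG; inputs are z-scored
#' with statistics stored in the returned model.
#'
#' @param features `n x 6` numeric matrix of input features (see
#'   [build_feature_matrix()]).
#' @param targets Length-`n` vector of verified adult heights in cm.
#' @param config An [mlp_config()].
#' @param log_every If positive, emit a `message` with the loss every this
#'   many iterations (0 = silent, the default).
#' @return An object of class `adult_height_mlp` holding the layer weights
#'   (`W1`, `b1`, `W2`, `b2`), the input scaling state (`center`, `scale`),
#'   the config, and the final training loss.
#' @export
train_adult_height_mlp <- function(features, targets, config = mlp_config(),
                                   log_every = 0L) {
  if (!inherits(config, "mlp_config")) stopf("`config` must be an mlp_config")
  features <- as.matrix(features)
  if (nrow(features) < 2L) stopf("need at least 2 training rows")
  if (nrow(features) != length(targets))
    stopf("features and targets disagree in length")
  if (anyNA(features) || any(!is.finite(features)) || any(!is.finite(targets)))
    stopf("non-finite values in the training batch")
  p <- ncol(features); h <- config$hidden_units
  n <- nrow(features)

  if (config$standardize_inputs) {
    ctr <- colMeans(features)
    scl <- apply(features, 2, stats::sd)
    scl[scl == 0] <- 1          # constant feature: leave centred at 0
  } else {
    ctr <- rep(0, p); scl <- rep(1, p)
  }
  X <- sweep(sweep(features, 2, ctr), 2, scl, `/`)
  d <- as.numeric(targets)

  state <- with_local_seed(config$seed, {
    list(W1 = he_uniform(p, h), b1 = numeric(h),
         W2 = he_uniform(h, 1L), b2 = mean(d))
  })
  W1 <- state$W1; b1 <- state$b1; W2 <- state$W2; b2 <- state$b2
  vW1 <- 0 * W1; vb1 <- 0 * b1; vW2 <- 0 * W2; vb2 <- 0
  lr <- config$learning_rate; mom <- config$momentum; band <- config$band

  loss <- NA_real_
  for (it in seq_len(config$iterations)) {
    Z1 <- sweep(X %*% W1, 2, b1, `+`)
    A1 <- pmax(Z1, 0)
    y <- drop(A1 %*% W2) + b2
    g <- band_loss_gradient(y, d, band)
    if (any(!is.finite(g)))
      stopf("non-finite loss gradient at iteration %d", it)
    gW2 <- crossprod(A1, g)
    gb2 <- sum(g)
    dA1 <- tcrossprod(g, W2) * (Z1 > 0)
    gW1 <- crossprod(X, dA1)
    gb1 <- colSums(dA1)
    if (mom > 0) {
      vW1 <- mom * vW1 + gW1; vb1 <- mom * vb1 + gb1
      vW2 <- mom * vW2 + gW2; vb2 <- mom * vb2 + gb2
      W1 <- W1 - lr * vW1; b1 <- b1 - lr * vb1
      W2 <- W2 - lr * vW2; b2 <- b2 - lr * vb2
    } else {
      W1 <- W1 - lr * gW1; b1 <- b1 - lr * gb1
      W2 <- W2 - lr * gW2; b2 <- b2 - lr * gb2
    }
    if (log_every > 0 && (it %% log_every == 0L || it == config$iterations)) {
      loss <- band_loss(y, d, band)
      message(sprintf("iter %d  band loss %.6f", it, loss))
    }
  }
  Z1 <- sweep(X %*% W1, 2, b1, `+`)
  y <- drop(pmax(Z1, 0) %*% W2) + b2
  structure(list(sex = config$sex, W1 = W1, b1 = b1, W2 = W2, b2 = b2,
                 center = ctr, scale = scl, config = config,
                 final_loss = band_loss(y, d, band), n_train = n),
            class = "adult_height_mlp")
}

#' @export
print.adult_height_mlp <- function(x, ...) {
  cat(sprintf(
    "Adult-height MLP (%s): 6 -> %d -> 1 (ReLU), trained on n = %d, final band loss %.4f cm^2\n",
    x$sex, ncol(x$W1), x$n_train, x$final_loss))
  invisible(x)
}

#' Predict adult height
#'
#' Forward pass through a trained network using its stored input scaling.
#'
#' @param model An `adult_height_mlp`.
#' @param features A length-6 feature vector or an `n x 6` matrix in the
#'   standard feature order (see [build_features()]).
#' @return Predicted adult height(s) in cm.
#' @export
predict_adult_height <- function(model, features) {
  if (!inherits(model, "adult_height_mlp"))
    stopf("`model` must be an adult_height_mlp")
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L)
  features <- as.matrix(features)
  if (ncol(features) != nrow(model$W1))
    stopf("feature dimension %d does not match the model's %d",
          ncol(features), nrow(model$W1))
  if (anyNA(features) || any(!is.finite(features)))
    stopf("non-finite feature values")
  X <- sweep(sweep(features, 2, model$center), 2, model$scale, `/`)
  A1 <- pmax(sweep(X %*% model$W1, 2, model$b1, `+`), 0)
  drop(A1 %*% model$W2) + model$b2
}

#' @rdname predict_adult_height
#' @param object An `adult_height_mlp`.
#' @param ... Unused.
#' @export
predict.adult_height_mlp <- function(object, features, ...) {
  predict_adult_height(object, features)
}

#' Split records into training and validation sets
#'
#' Seeded shuffle followed by an exact partition: the validation set gets
#' `floor(n * (1 - ratio))` records and the training set the rest, so a
#' 3:1 split of 615 records yields sizes 462 and 153.
#'
#' @param records A data frame (or anything indexable by row) to split.
#' @param ratio Training fraction in (0, 1); default 0.75 (a 3:1 split).
#' @param seed Integer seed making the shuffle reproducible.
#' @return A list with elements `train` and `validation`.
#' @export
split_train_validation <- function(records, ratio = 0.75, seed = 1L) {
  check_number(ratio, "ratio", 0, 1, open_lower = TRUE, open_upper = TRUE)
  n <- nrow(records)
  if (is.null(n)) stopf("`records` must be a data frame or matrix")
  if (n < 2L) stopf("need at least 2 records to split, got %d", n)
  n_val <- floor(n * (1 - ratio))
  idx <- with_local_seed(seed, sample.int(n))
  val_idx <- if (n_val > 0) sort(idx[seq_len(n_val)]) else integer(0)
  train_idx <- sort(idx[setdiff(seq_len(n), seq_len(n_val))])
  list(train = records[train_idx, , drop = FALSE],
       validation = records[val_idx, , drop = FALSE])
}

#' Serialize / read a trained network as JSON
#'
#' Stores shapes, weights, the input scaling state, and the configuration
#' (including the seed), so a model round-trips exactly through text.
#'
#' @param model An `adult_height_mlp`.
#' @param path File path.
#' @return `write_mlp_model` returns `path` invisibly; `read_mlp_model`
#'   returns the model.
#' @export
write_mlp_model <- function(model, path) {
  if (!inherits(model, "adult_height_mlp"))
    stopf("`model` must be an adult_height_mlp")
  cfg <- unclass(model$config)
  jsonlite::write_json(
    list(sex = model$sex,
         W1 = model$W1, b1 = model$b1,
         W2 = as.numeric(model$W2), b2 = model$b2,
         center = model$center, scale = model$scale,
         config = cfg, final_loss = model$final_loss,
         n_train = model$n_train),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mlp_model
#' @export
read_mlp_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(mlp_config, obj$config[c("sex", "hidden_units",
                                          "learning_rate", "iterations",
                                          "band", "momentum",
                                          "standardize_inputs", "seed")])
  structure(list(sex = obj$sex,
                 W1 = matrix(obj$W1, nrow = nrow(obj$W1)),
                 b1 = as.numeric(obj$b1),
                 W2 = matrix(obj$W2, ncol = 1L),
                 b2 = obj$b2,
                 center = as.numeric(obj$center),
                 scale = as.numeric(obj$scale),
                 config = cfg, final_loss = obj$final_loss,
                 n_train = obj$n_train),
            class = "adult_height_mlp")
}
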