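#' Hidden-layer transfer functions
#'
#' The three hidden-unit activations compared for the price network:
#' saturating linear (`clamp(x, -1, 1)`), hyperbolic tangent, and the
#' logistic sigmoid. The output unit is always the identity (standard for
#' regression; it avoids saturating the 30-220 RMB/kg range).
#'
#' @param name One of `"linear_sat"`, `"tanh"`, `"logistic"`.
#' @return A list with `name`, `f` (forward map) and `df` (derivative).
#' @export
transfer_function <- function(name) {
  switch(name,
    linear_sat = list(
      name = "linear_sat",
      f = function(x) pmin(pmax(x, -1), 1),
      df = function(x) as.numeric(x > -1 & x < 1)
    ),
    tanh = list(
      name = "tanh",
      f = tanh,
      df = function(x) 1 - tanh(x)^2
    ),
    logistic = list(
      name = "logistic",
      f = function(x) 1 / (1 + exp(-x)),
      df = function(x) {
        s <- 1 / (1 + exp(-x))
        s * (1 - s)
      }
    ),
    abort(sprintf(
      "Unknown transfer '%s' (use linear_sat, tanh or logistic).", name))
  )
}

#' Training configuration for the back-propagation network
#'
#' @param learning_rate Gradient-descent step size.
#' @param momentum Momentum coefficient.
#' @param epochs Full-batch epochs.
#' @param n_hidden Hidden-layer size (5 in the reference architecture).
#' @param cv_epochs Reduced epoch budget used when leave-one-out
#'   retraining computes RMSECV.
#' @param seed Integer seed for the uniform `[-0.5, 0.5]` weight draw.
#' @return A list of class `bpann_config`.
#' @export
bpann_config <- function(learning_rate = 0.05, momentum = 0.9,
                         epochs = 2000, n_hidden = 5, cv_epochs = 500,
                         seed = 1L) {
  assert_number(learning_rate, "learning_rate", positive = TRUE)
  assert_number(momentum, "momentum")
  if (momentum < 0 || momentum >= 1) abort("`momentum` must be in [0, 1).")
  structure(
    list(learning_rate = learning_rate, momentum = momentum,
         epochs = assert_count(epochs, "epochs"),
         n_hidden = assert_count(n_hidden, "n_hidden"),
         cv_epochs = assert_count(cv_epochs, "cv_epochs"),
         seed = as.integer(seed)),
    class = "bpann_config"
  )
}

# Affine scaler x -> lo + (hi - lo) * (x - min) / (max - min), columnwise.
make_scaler <- function(X, lo, hi) {
  mins <- apply(X, 2, min)
  maxs <- apply(X, 2, max)
  span <- maxs - mins
  span[span == 0] <- 1 # constant feature maps to lo
  list(mins = mins, span = span, lo = lo, hi = hi)
}

scale_fwd <- function(scaler, X) {
  sweep(sweep(X, 2, scaler$mins), 2, scaler$span, "/") *
    (scaler$hi - scaler$lo) + scaler$lo
}

scale_inv <- function(scaler, Z) {
  Z <- as.matrix(Z)
  sweep(sweep((Z - scaler$lo) / (scaler$hi - scaler$lo), 2, scaler$span, "*"),
        2, scaler$mins, "+")
}

# Forward pass on scaled inputs. params: list(W1 h x k, b1, W2 1 x h, b2).
bpann_forward <- function(params, Xs, tf) {
  Z1 <- Xs %*% t(params$W1) + rep(params$b1, each = nrow(Xs))
  A1 <- tf$f(Z1)
  pred <- drop(A1 %*% t(params$W2)) + params$b2
  list(Z1 = Z1, A1 = A1, pred = pred)
}

# Loss 0.5 * mean((pred - t)^2) and its gradient w.r.t. all parameters.
bpann_loss_grad <- function(params, Xs, targets, tf) {
  n <- nrow(Xs)
  fw <- bpann_forward(params, Xs, tf)
  err <- fw$pred - targets
  loss <- 0.5 * mean(err^2)
  d_out <- matrix(err / n, ncol = 1)
  gW2 <- crossprod(d_out, fw$A1)
  gb2 <- sum(d_out)
  D1 <- (d_out %*% params$W2) * tf$df(fw$Z1)
  gW1 <- crossprod(D1, Xs)
  gb1 <- colSums(D1)
  list(loss = loss,
       grad = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2))
}

#' Train the 3-5-1 back-propagation price network
#'
#' Inputs (principal-component scores) are affinely scaled per feature to
#' `[-1, 1]` from the training extremes; prices are scaled to
#' `[0.1, 0.9]` of the training range. Weights start uniform in
#' `[-0.5, 0.5]` from the seed, then full-batch gradient descent with
#' momentum minimizes squared error; the returned model is the epoch with
#' the lowest training RMSE.
#'
#' @param scores Numeric matrix of network inputs (`n >= 10` rows).
#' @param prices Positive response vector (RMB/kg).
#' @param transfer Hidden transfer name, see [transfer_function()].
#' @param config A [bpann_config()].
#' @return An object of class `bpann_model`.
#' @export
train_bpann <- function(scores, prices, transfer = "logistic",
                        config = bpann_config()) {
  if (!is.matrix(scores)) scores <- as.matrix(scores)
  n <- nrow(scores)
  if (n < 10) abort("Training needs at least 10 samples.")
  if (length(prices) != n) abort("`prices` length must match `scores` rows.")
  if (any(prices <= 0)) abort("`prices` must be positive.")
  tf <- transfer_function(transfer)
  k <- ncol(scores)
  h <- config$n_hidden

  in_scaler <- make_scaler(scores, -1, 1)
  out_scaler <- make_scaler(matrix(prices, ncol = 1), 0.1, 0.9)
  Xs <- scale_fwd(in_scaler, scores)
  targets <- drop(scale_fwd(out_scaler, matrix(prices, ncol = 1)))

  params <- with_seed(config$seed, list(
    W1 = matrix(runif(h * k, -0.5, 0.5), h, k),
    b1 = runif(h, -0.5, 0.5),
    W2 = matrix(runif(h, -0.5, 0.5), 1, h),
    b2 = runif(1, -0.5, 0.5)
  ))
  vel <- lapply(params, function(p) p * 0)
  best <- list(loss = Inf, params = params)
  for (epoch in seq_len(config$epochs)) {
    lg <- bpann_loss_grad(params, Xs, targets, tf)
    if (!is.finite(lg$loss)) {
      abort("Training diverged (non-finite loss); try a smaller learning rate.")
    }
    if (lg$loss < best$loss) best <- list(loss = lg$loss, params = params)
    for (nm in names(params)) {
      vel[[nm]] <- config$momentum * vel[[nm]] -
        config$learning_rate * lg$grad[[nm]]
      params[[nm]] <- params[[nm]] + vel[[nm]]
    }
  }
  lg <- bpann_loss_grad(params, Xs, targets, tf)
  if (is.finite(lg$loss) && lg$loss < best$loss) {
    best <- list(loss = lg$loss, params = params)
  }

  structure(
    list(params = best$params, transfer = tf$name,
         in_scaler = in_scaler, out_scaler = out_scaler,
         n_inputs = k, n_hidden = h, config = config,
         train_loss = best$loss),
    class = "bpann_model"
  )
}

#' Predict prices with a trained network
#'
#' Forward pass on scaled inputs followed by the inverse target scaling.
#'
#' @param model A `bpann_model`.
#' @param scores Numeric matrix (or vector) with the training input width.
#' @return Numeric vector of prices (RMB/kg).
#' @export
predict_price <- function(model, scores) {
  stopifnot(inherits(model, "bpann_model"))
  if (!is.matrix(scores)) scores <- matrix(scores, nrow = 1)
  if (ncol(scores) != model$n_inputs) {
    abort(sprintf("`scores` has %d columns; the model expects %d.",
                  ncol(scores), model$n_inputs))
  }
  tf <- transfer_function(model$transfer)
  Xs <- scale_fwd(model$in_scaler, scores)
  pred <- bpann_forward(model$params, Xs, tf)$pred
  drop(scale_inv(model$out_scaler, matrix(pred, ncol = 1)))
}

#' @export
predict.bpann_model <- function(object, newdata, ...) {
  predict_price(object, newdata)
}

#' @export
print.bpann_model <- function(x, ...) {
  cat(sprintf("<bpann_model> %d-%d-1, %s transfer, train loss %.3g\n",
              x$n_inputs, x$n_hidden, x$transfer, x$train_loss))
  invisible(x)
}

#' One-row summary of a trained network
#' @param x A `bpann_model`.
#' @param ... Unused.
#' @return A tibble with architecture, transfer and final training loss.
#' @method glance bpann_model
#' @export
glance.bpann_model <- function(x, ...) {
  tibble(n_inputs = x$n_inputs, n_hidden = x$n_hidden,
         transfer = x$transfer, train_loss = x$train_loss,
         epochs = x$config$epochs)
}

# Leave-one-out RMSECV/R2cv for one transfer, retraining with a reduced
# epoch budget.
bpann_loo <- function(scores, prices, transfer, config) {
  n <- nrow(scores)
  cfg <- config
  cfg$epochs <- config$cv_epochs
  preds <- numeric(n)
  for (i in seq_len(n)) {
    fit <- train_bpann(scores[-i, , drop = FALSE], prices[-i], transfer, cfg)
    preds[i] <- predict_price(fit, scores[i, , drop = FALSE])
  }
  preds
}

#' Compare the three transfer functions
#'
#' Trains one network per transfer on the calibration scores, computes
#' calibration RMSECV/R^2cv by leave-one-out retraining (with the reduced
#' `cv_epochs` budget) and prediction-set RMSEP/R^2p from the held-out
#' scores.
#'
#' @param scores_train,y_train Calibration scores and prices.
#' @param scores_pred,y_pred Prediction-set scores and prices (must be
#'   disjoint from the calibration rows).
#' @param config A [bpann_config()].
#' @param transfers Transfer names to compare.
#' @param cv Compute the leave-one-out columns (set `FALSE` to skip the
#'   retraining loop and report prediction metrics only).
#' @return A tibble with one row per transfer: `transfer`, `rc2`,
#'   `rmsecv`, `rp2`, `rmsep`.
#' @export
compare_transfers <- function(scores_train, y_train, scores_pred, y_pred,
                              config = bpann_config(),
                              transfers = c("linear_sat", "tanh", "logistic"),
                              cv = TRUE) {
  scores_train <- as.matrix(scores_train)
  scores_pred <- as.matrix(scores_pred)
  key <- function(M) apply(round(M, 10), 1, paste, collapse = ",")
  if (any(key(scores_train) %in% key(scores_pred))) {
    abort("Calibration and prediction sets overlap.")
  }
  purrr::map_dfr(transfers, function(tr) {
    fit <- train_bpann(scores_train, y_train, tr, config)
    pp <- predict_price(fit, scores_pred)
    row <- tibble(
      transfer = tr,
      rc2 = NA_real_, rmsecv = NA_real_,
      rp2 = r_squared(y_pred, pp),
      rmsep = rmse(y_pred, pp)
    )
    if (cv) {
      cvp <- bpann_loo(scores_train, y_train, tr, config)
      row$rc2 <- r_squared(y_train, cvp)
      row$rmsecv <- rmse(y_train, cvp)
    }
    row
  })
}
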