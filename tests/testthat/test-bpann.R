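test_that("transfer functions satisfy their range and derivative contracts", {
  for (nm in c("linear_sat", "tanh", "logistic")) {
    tf <- transfer_function(nm)
    x <- seq(-4, 4, by = 0.37) # avoids the clamp kinks at exactly +-1
    if (nm == "logistic") expect_true(all(tf$f(x) > 0 & tf$f(x) < 1))
    if (nm == "tanh") expect_true(all(tf$f(x) > -1 & tf$f(x) < 1))
    if (nm == "linear_sat") {
      expect_equal(tf$f(c(-3, 0.5, 3)), c(-1, 0.5, 1))
    }
    fd <- (tf$f(x + 1e-6) - tf$f(x - 1e-6)) / 2e-6
    expect_equal(tf$df(x), fd, tolerance = 1e-5)
  }
  expect_equal(transfer_function("logistic")$f(0), 0.5)
  expect_error(transfer_function("relu"), "Unknown transfer")
})

test_that("back-propagated gradients match central finite differences", {
  withr::with_seed(61, {
    for (nm in c("linear_sat", "tanh", "logistic")) {
      tf <- transfer_function(nm)
      params <- list(W1 = matrix(runif(15, -0.5, 0.5), 5, 3),
                     b1 = runif(5, -0.5, 0.5),
                     W2 = matrix(runif(5, -0.5, 0.5), 1, 5),
                     b2 = runif(1, -0.5, 0.5))
      Xs <- matrix(runif(36, -0.9, 0.9), 12, 3)
      tg <- runif(12, 0.1, 0.9)
      lg <- leafprice:::bpann_loss_grad(params, Xs, tg, tf)
      eps <- 1e-6
      for (pname in names(params)) {
        for (idx in seq_along(params[[pname]])) {
          pp <- params
          pp[[pname]][idx] <- pp[[pname]][idx] + eps
          up <- leafprice:::bpann_loss_grad(pp, Xs, tg, tf)$loss
          pp[[pname]][idx] <- pp[[pname]][idx] - 2 * eps
          dn <- leafprice:::bpann_loss_grad(pp, Xs, tg, tf)$loss
          num <- (up - dn) / (2 * eps)
          denom <- max(abs(num), abs(lg$grad[[pname]][idx]), 1e-8)
          expect_lt(abs(num - lg$grad[[pname]][idx]) / denom, 1e-6)
        }
      }
    }
  })
})

test_that("a linear response is fit essentially perfectly", {
  withr::with_seed(62, {
    S <- matrix(runif(42 * 3, -0.8, 0.8), 42, 3)
    y <- 120 + 40 * S[, 1] - 25 * S[, 2] + 10 * S[, 3]
  })
  fit <- train_bpann(S, y, "linear_sat", bpann_config(seed = 4))
  r2 <- r_squared(y, predict_price(fit, S))
  expect_gt(r2, 0.999)
  # and the OLS oracle confirms the response is exactly linear
  cf <- pinv(cbind(1, S)) %*% y
  expect_lt(rmse(y, drop(cbind(1, S) %*% cf)), 1e-8)
})

test_that("training is seeded, monotone in budget, and validates input", {
  withr::with_seed(63, {
    S <- matrix(runif(36 * 3, -1, 1), 36, 3)
    y <- 100 + 30 * tanh(2 * S[, 1]) - 20 * S[, 2] + rnorm(36, sd = 2)
  })
  m1 <- train_bpann(S, y, "logistic", bpann_config(seed = 11))
  m2 <- train_bpann(S, y, "logistic", bpann_config(seed = 11))
  expect_identical(m1$params, m2$params)

  short <- train_bpann(S, y, "logistic",
                       bpann_config(epochs = 50, seed = 11))
  long <- train_bpann(S, y, "logistic",
                      bpann_config(epochs = 2000, seed = 11))
  expect_lte(long$train_loss, short$train_loss) # epoch-best is monotone

  expect_error(train_bpann(S[1:5, ], y[1:5], "tanh"), "at least 10")
  expect_error(train_bpann(S, y - 200, "tanh"), "positive")
  expect_error(train_bpann(S, y, "relu"), "Unknown transfer")
})

test_that("prediction inverts the target scaling", {
  withr::with_seed(64, {
    S <- matrix(runif(30 * 3, -1, 1), 30, 3)
    y <- runif(30, 30, 220)
  })
  fit <- train_bpann(S, y, "tanh", bpann_config(epochs = 200, seed = 2))
  # zero hidden weights: the forward pass reduces to the bias path
  fit0 <- fit
  fit0$params$W2 <- matrix(0, 1, 5)
  expect_equal(
    unname(predict_price(fit0, S)),
    rep(unname(drop(leafprice:::scale_inv(
      fit0$out_scaler, matrix(fit0$params$b2, 1, 1)))), 30)
  )
  expect_error(predict_price(fit, matrix(0, 1, 4)), "expects")
  # predictions stay finite over the training hull
  expect_true(all(is.finite(predict_price(fit, S))))
})

test_that("transfer comparison reports consistent metrics per row", {
  withr::with_seed(65, {
    S <- matrix(runif(40 * 3, -1, 1), 40, 3)
    y <- 100 + 45 * S[, 1] - 30 * S[, 2]^2 + 15 * S[, 3] + rnorm(40, 2)
  })
  tb <- compare_transfers(S[1:28, ], y[1:28], S[29:40, ], y[29:40],
                          bpann_config(epochs = 600, cv_epochs = 150,
                                       seed = 3))
  expect_equal(nrow(tb), 3)
  expect_true(all(is.finite(unlist(tb[, c("rc2", "rmsecv", "rp2",
                                          "rmsep")]))))
  # rp2 is recomputable from rmsep on the same held-out set
  ss <- sum((y[29:40] - mean(y[29:40]))^2)
  expect_equal(tb$rp2, 1 - 12 * tb$rmsep^2 / ss, tolerance = 1e-10)
  expect_error(
    compare_transfers(S[1:28, ], y[1:28], S[c(1, 29:39), ],
                      y[c(1, 29:39)], bpann_config(seed = 3)),
    "overlap"
  )
})

test_that("nonlinear transfers handle a saturating response better", {
  # hidden pre-activations reach past the clamp's linear range, so the
  # saturating-linear net plateaus while tanh/logistic keep resolving
  res <- vapply(1:10, function(s) {
    withr::with_seed(1000 + s, {
      S <- matrix(runif(40 * 3, -1, 1), 40, 3)
      y <- 120 + 60 * tanh(2.5 * S[, 1] + 1.5 * S[, 2]) + rnorm(40, 3)
    })
    cfg <- bpann_config(epochs = 800, seed = s)
    tr <- train_bpann(S[1:28, ], y[1:28], "linear_sat", cfg)
    nl <- train_bpann(S[1:28, ], y[1:28], "logistic", cfg)
    rmse(y[29:40], predict_price(tr, S[29:40, ])) -
      rmse(y[29:40], predict_price(nl, S[29:40, ]))
  }, numeric(1))
  expect_gte(stats::median(res), 0)
})
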