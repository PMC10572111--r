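test_that("one-column PLS reduces to simple linear regression", {
  withr::with_seed(1, {
    x <- rnorm(20)
    y <- 3 + 2 * x + rnorm(20, sd = 0.3)
    fit <- fit_pls(matrix(x, ncol = 1), y, 1)
    cf <- ols_simple(x, y)
    expect_equal(predict(fit, matrix(x, ncol = 1)),
                 unname(cf["intercept"] + cf["slope"] * x),
                 tolerance = 1e-10)
  })
})

test_that("full-factor PLS equals multivariate least squares", {
  withr::with_seed(2, {
    X <- matrix(rnorm(15 * 4), 15, 4)
    y <- rnorm(15)
    fit <- fit_pls(X, y, 4)
    Xc <- sweep(X, 2, colMeans(X))
    b_ls <- pinv(Xc) %*% (y - mean(y))
    expect_equal(predict(fit, X), drop(mean(y) + Xc %*% b_ls),
                 tolerance = 1e-8)
  })
})

test_that("NIPALS agrees with the SVD-route PLS oracle", {
  withr::with_seed(3, {
    for (rep in 1:5) {
      X <- matrix(rnorm(18 * 7), 18, 7)
      y <- rnorm(18)
      a <- sample(1:4, 1)
      fit <- fit_pls(X, y, a)
      oracle <- svd_pls1(X, y, a)
      expect_equal(fit$coefficients[, a], oracle$coef, tolerance = 1e-8)
    }
  })
})

test_that("NIPALS agrees with mixOmics on training predictions", {
  skip_if_not_installed("mixOmics")
  withr::with_seed(4, {
    X <- matrix(rnorm(20 * 8), 20, 8,
                dimnames = list(NULL, paste0("v", 1:8)))
    y <- rnorm(20)
    fit <- fit_pls(X, y, 3)
    mo <- mixOmics::pls(X, y, ncomp = 3, mode = "regression",
                        scale = FALSE)
    mo_pred <- predict(mo, X)$predict[, 1, 3]
    expect_equal(predict(fit, X), unname(mo_pred), tolerance = 1e-8)
  })
})

test_that("exactly linear responses are recovered to machine precision", {
  withr::with_seed(5, {
    X <- matrix(rnorm(30 * 6), 30, 6)
    y <- drop(X %*% c(1, -2, 0.5, 0, 3, -1)) + 7
    fit <- fit_pls(X, y, 6)
    expect_lt(rmse(y, predict(fit, X)), 1e-8)
  })
})

test_that("prediction respects centering and rejects bad inputs", {
  withr::with_seed(6, {
    X <- matrix(rnorm(12 * 3), 12, 3)
    y <- rnorm(12)
    fit <- fit_pls(X, y, 2)
    expect_equal(predict(fit, fit$x_mean), mean(y))
    two <- rbind(X[1, ], X[1, ])
    expect_equal(predict(fit, two)[1], predict(fit, two)[2])
    expect_error(predict(fit, matrix(0, 1, 5)), "expects")
    expect_error(fit_pls(X, rep(1, 12), 2), "zero variance")
    expect_error(fit_pls(X, y, 12), "min")
  })
})

test_that("error metrics follow their definitions", {
  expect_equal(rmse(c(1, 2), c(1, 2)), 0)
  expect_equal(rmse(c(0, 0), c(3, -3)), 3)
  expect_error(rmse(1:3, 1:2), "length")
  expect_equal(r_squared(1:5, 1:5), 1)
  expect_equal(r_squared(c(1, 2, 3), rep(2, 3)), 0)
  expect_error(r_squared(rep(2, 4), 1:4), "constant")
  # algebraic identity: R2 = 1 - n rmse^2 / SS_tot
  withr::with_seed(7, {
    yt <- rnorm(15); yp <- yt + rnorm(15, sd = 0.5)
    expect_equal(r_squared(yt, yp),
                 1 - 15 * rmse(yt, yp)^2 / sum((yt - mean(yt))^2))
  })
  expect_equal(percent_change(0.526, 0.732), 39.16, tolerance = 1e-3)
})

test_that("leave-one-out CV matches an explicit refit loop", {
  withr::with_seed(8, {
    x <- rnorm(14)
    y <- 1 + 0.5 * x + rnorm(14, sd = 0.2)
    got <- cross_validate(matrix(x, ncol = 1), y, 1, cv_loo())
    loo <- vapply(seq_along(y), function(i) {
      cf <- ols_simple(x[-i], y[-i])
      unname(cf["intercept"] + cf["slope"] * x[i])
    }, numeric(1))
    expect_equal(got$rmsecv, rmse(y, loo), tolerance = 1e-10)
    expect_equal(got$r2cv, r_squared(y, loo), tolerance = 1e-10)
  })
})

test_that("cross-validation is deterministic and guards its folds", {
  withr::with_seed(9, {
    X <- matrix(rnorm(20 * 5), 20, 5)
    y <- rnorm(20)
    a <- cross_validate(X, y, 3, cv_kfold(4, seed = 11))
    b <- cross_validate(X, y, 3, cv_kfold(4, seed = 11))
    expect_identical(a, b)
    expect_error(cross_validate(X, y, 3, cv_kfold(25, seed = 1)),
                 "exceed")
    # zero-noise affine response cross-validates to ~0 error
    y0 <- drop(X %*% c(1, 2, 3, 4, 5))
    expect_lt(cross_validate(X, y0, 5, cv_loo())$rmsecv, 1e-6)
  })
})

test_that("factor selection is parsimonious and order-invariant", {
  withr::with_seed(10, {
    # response spanned by two orthogonal latent directions, zero noise
    n <- 24
    t1 <- rnorm(n); t2 <- rnorm(n)
    X <- cbind(t1, t1, t2, t2, t2)
    y <- 2 * t1 - t2
    nf <- select_factors(X, y, 5, cv_loo())
    expect_lte(as.integer(nf), 2)

    X2 <- matrix(rnorm(n * 4), n, 4)
    y2 <- rnorm(n)
    expect_equal(as.integer(select_factors(X2, y2, 1, cv_loo())), 1L)
    perm <- sample(n)
    expect_equal(as.integer(select_factors(X2, y2, 4, cv_loo())),
                 as.integer(select_factors(X2[perm, ], y2[perm], 4,
                                           cv_loo())))
  })
})

test_that("training R2 is non-decreasing in the factor count", {
  withr::with_seed(12, {
    X <- matrix(rnorm(25 * 8), 25, 8)
    y <- rnorm(25)
    fit <- fit_pls(X, y, 8)
    r2s <- vapply(1:8, function(a) {
      r_squared(y, predict(fit, X, n_factors = a))
    }, numeric(1))
    expect_true(all(diff(r2s) >= -1e-12))
  })
})
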