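test_that("si-PLS equals brute-force enumeration on a toy problem", {
  withr::with_seed(31, {
    grid <- nir_grid(8000, 10, 12)
    X <- matrix(rnorm(40 * 12), 40, 12)
    y <- drop(X %*% rnorm(12)) + rnorm(40, sd = 0.5)
    res <- sipls_search(X, y, grid, interval_counts = 4, combo_size = 2,
                       max_factors = 4, scheme = cv_loo())
    # independent enumeration of all C(4,2) = 6 combinations
    part <- partition_intervals(12, 4)
    oracle <- lapply(asplit(combn(4, 2), 2), function(combo) {
      cols <- interval_columns(part, combo, 12)
      nf <- select_factors(X[, cols, drop = FALSE], y, 4, cv_loo())
      list(combo = as.integer(combo),
           rmsecv = attr(nf, "trace")$rmsecv[nf],
           n_factors = as.integer(nf))
    })
    best <- oracle[[which.min(vapply(oracle, `[[`, numeric(1), "rmsecv"))]]
    expect_equal(res$best$combo, best$combo)
    expect_equal(res$best$rmsecv, best$rmsecv, tolerance = 1e-12)
    expect_equal(res$best$n_factors, best$n_factors)
  })
})

test_that("si-PLS recovers planted informative intervals", {
  # two bands carry all the price signal; no scatter, no decoy variance
  bands <- tibble::tibble(
    center = c(5100, 6900, 4600, 7550),
    width = c(120, 150, 60, 60),
    amplitude = c(1.8, 1.5, 0.3, 0.25),
    role = c("water", "water", "price", "price"),
    conc_base = c(NA, NA, 0, 0),
    conc_per_price = c(NA, NA, 1 / 220, 1 / 220),
    conc_sd = c(NA, NA, 0.01, 0.01)
  )
  cfg <- fast_cfg(bands = bands, scatter_slope_sd = 0,
                  scatter_offset_sd = 0, scatter_tilt_sd = 0, seed = 3)
  set <- generate_dataset(cfg)
  cal <- subset_samples(set, "calibration")
  res <- sipls_search(cal$absorbance, cal$samples$price, set$grid,
                      interval_counts = 16, combo_size = 2,
                      max_factors = 6, scheme = cv_loo())
  wn <- intervals_to_wavenumbers(partition_intervals(set$grid$n_points, 16),
                                 res$best$combo, set$grid)
  covers <- function(center) {
    any(wn$wn_low - 40 <= center & center <= wn$wn_high + 40)
  }
  expect_true(covers(4600))
  expect_true(covers(7550))
})

test_that("infeasible interval counts are skipped with a warning", {
  withr::with_seed(32, {
    grid <- nir_grid(8000, 10, 12)
    X <- matrix(rnorm(30 * 12), 30, 12)
    y <- rnorm(30)
    expect_warning(
      res <- sipls_search(X, y, grid, interval_counts = c(3, 5),
                          combo_size = 4, max_factors = 3,
                          scheme = cv_loo()),
      "skipping"
    )
    expect_equal(res$table$n_intervals, 5L)
    expect_error(
      suppressWarnings(sipls_search(X, y, grid, interval_counts = 3,
                                    combo_size = 4, scheme = cv_loo())),
      "No interval count"
    )
  })
})

test_that("widening the interval-count range never worsens the optimum", {
  withr::with_seed(33, {
    grid <- nir_grid(9000, 25, 40)
    X <- matrix(rnorm(30 * 40), 30, 40)
    y <- drop(X[, c(5, 20)] %*% c(2, -1)) + rnorm(30, sd = 0.3)
    narrow <- sipls_search(X, y, grid, interval_counts = 5:6,
                           combo_size = 2, max_factors = 4,
                           scheme = cv_loo())
    wide <- sipls_search(X, y, grid, interval_counts = 4:8,
                         combo_size = 2, max_factors = 4,
                         scheme = cv_loo())
    expect_lte(wide$best$rmsecv, narrow$best$rmsecv)
  })
})

test_that("the search is bit-for-bit reproducible under leave-one-out", {
  withr::with_seed(34, {
    grid <- nir_grid(9000, 25, 24)
    X <- matrix(rnorm(25 * 24), 25, 24)
    y <- rnorm(25)
    r1 <- sipls_search(X, y, grid, interval_counts = 4:6, combo_size = 2,
                       max_factors = 3, scheme = cv_loo())
    r2 <- sipls_search(X, y, grid, interval_counts = 4:6, combo_size = 2,
                       max_factors = 3, scheme = cv_loo())
    expect_identical(r1$table, r2$table)
  })
})

test_that("si-PLS summaries expose the interval-count table", {
  withr::with_seed(35, {
    grid <- nir_grid(9000, 25, 24)
    X <- matrix(rnorm(25 * 24), 25, 24)
    y <- drop(X %*% rnorm(24))
    res <- sipls_search(X, y, grid, interval_counts = 4:6, combo_size = 2,
                        max_factors = 3, scheme = cv_loo())
    td <- tidy(res)
    expect_equal(nrow(td), 3)
    expect_match(td$combo[1], "^\\[\\d+ \\d+\\]$")
    gl <- glance(res)
    expect_equal(gl$rmsecv, min(td$rmsecv))
    expect_equal(gl$n_points, length(sipls_columns(res)))
    expect_s3_class(autoplot(res), "ggplot")
  })
})
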