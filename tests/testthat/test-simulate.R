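test_that("grade targets interpolate the QI and price endpoints linearly", {
  cfg <- fast_cfg()
  tg <- grade_targets(1:7, cfg)
  expect_equal(tg$qi[1], 0.552)
  expect_equal(tg$price[1], 220)
  expect_equal(tg$qi[7], 0.383)
  expect_equal(tg$price[7], 30)
  expect_equal(tg$qi[4], (0.552 + 0.383) / 2)
  expect_equal(tg$price[4], 125)
  expect_error(grade_targets(0, cfg), "1..7")
  expect_error(grade_targets(8, cfg), "1..7")
})

test_that("the QI identity holds exactly for every generated profile", {
  cfg0 <- fast_cfg(qi_sd = 0, humidity_sd = 0, price_jitter_sd = 0)
  prof <- withr::with_seed(1, generate_constituents(1, cfg0))
  expect_equal(quality_index(prof$humidity, prof$total_nitrogen,
                             prof$crude_fiber), 0.552)
  # with noise the identity still holds for the drawn values
  cfg <- fast_cfg()
  prof2 <- withr::with_seed(2, generate_constituents(5, cfg))
  expect_equal(quality_index(prof2$humidity, prof2$total_nitrogen,
                             prof2$crude_fiber), prof2$qi)
  # same RNG state, same profile
  p1 <- withr::with_seed(7, generate_constituents(3, cfg))
  p2 <- withr::with_seed(7, generate_constituents(3, cfg))
  expect_identical(p1, p2)
})

test_that("spectra are band mixtures with dominant water peaks", {
  cfg <- fast_cfg(noise_sd = 0, scatter_slope_sd = 0,
                  scatter_offset_sd = 0, scatter_tilt_sd = 0,
                  qi_sd = 0, humidity_sd = 0, price_jitter_sd = 0)
  grid <- nir_grid(cfg$max_wavenumber, cfg$step, cfg$n_points)

  # single unit band reproduces its Gaussian profile exactly
  bands1 <- tibble::tibble(center = 6000, width = 100, amplitude = 0.7,
                           role = "decoy", conc_base = 1,
                           conc_per_price = 0, conc_sd = 0)
  prof <- list(band_conc = 1)
  spec <- generate_spectrum(prof, grid, bands1)
  expect_equal(spec, 0.7 * exp(-(grid$values - 6000)^2 / (2 * 100^2)))
  # doubling the scatter slope doubles the band term but not the offset
  s2 <- generate_spectrum(prof, grid, bands1, scatter = c(2, 0.3, 0))
  expect_equal(s2 - 0.3, 2 * spec)

  # argmax of a default zero-noise spectrum sits on a water band
  profile <- withr::with_seed(1, generate_constituents(4, cfg))
  full <- generate_spectrum(profile, grid, cfg$bands)
  peak_wn <- grid$values[which.max(full)]
  expect_true(min(abs(peak_wn - c(5100, 6900))) <= 2 * grid$step)

  # band outside the grid span is rejected
  bad <- bands1; bad$center <- 12000
  expect_error(generate_spectrum(prof, grid, bad), "span")
})

test_that("generated datasets have the study's shape and are reproducible", {
  cfg <- fast_cfg(seed = 31)
  set <- generate_dataset(cfg)
  expect_equal(nrow(set$absorbance), 70L) # 56 graded + 14 external
  expect_equal(sum(set$samples$split == "external"), 14L)
  expect_equal(sum(!is.na(set$samples$grade)), 56L)
  expect_true(all(set$samples$price > 0))

  set2 <- generate_dataset(cfg)
  expect_identical(set$absorbance, set2$absorbance)
  expect_identical(set$samples, set2$samples)

  # zero noise everywhere -> within-grade spectra identical
  cfg0 <- fast_cfg(noise_sd = 0, scatter_slope_sd = 0,
                   scatter_offset_sd = 0, scatter_tilt_sd = 0, qi_sd = 0,
                   humidity_sd = 0, price_jitter_sd = 0, seed = 5,
                   bands = dplyr::mutate(default_bands(), conc_sd = 0))
  set0 <- generate_dataset(cfg0)
  g1 <- set0$absorbance[which(set0$samples$grade == 1), ]
  expect_lt(max(abs(sweep(g1, 2, g1[1, ]))), 1e-12)
})

test_that("price is linear in grade: exact at zero noise, R2 >= 0.99 at default", {
  cfg0 <- fast_cfg(price_jitter_sd = 0, seed = 2)
  set0 <- generate_dataset(cfg0)
  graded <- set0$samples[!is.na(set0$samples$grade), ]
  expect_equal(linear_fit_report(graded$grade, graded$price)$r_squared, 1)

  ok <- vapply(1:100, function(s) {
    set <- generate_dataset(fast_cfg(seed = s))
    d <- set$samples[!is.na(set$samples$grade), ]
    linear_fit_report(d$grade, d$price)$r_squared >= 0.99
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("full-spectrum PLS recovers price exactly in the noiseless limit", {
  cfg0 <- fast_cfg(noise_sd = 0, scatter_slope_sd = 0,
                   scatter_offset_sd = 0, scatter_tilt_sd = 0, qi_sd = 0,
                   humidity_sd = 0, seed = 8,
                   bands = dplyr::mutate(default_bands(), conc_sd = 0))
  set0 <- generate_dataset(cfg0)
  cal <- subset_samples(set0, "calibration")
  cv <- cross_validate(cal$absorbance, cal$samples$price,
                       n_factors = 4, scheme = cv_loo())
  expect_lt(cv$rmsecv, 1)
})

test_that("multiplicative scatter degrades full-spectrum PLS on average", {
  rmsecv_at <- function(slope_sd, seed) {
    set <- generate_dataset(fast_cfg(scatter_slope_sd = slope_sd,
                                     seed = seed))
    cal <- subset_samples(set, "calibration")
    nf <- select_factors(cal$absorbance, cal$samples$price, 8, cv_loo())
    attr(nf, "trace")$rmsecv[nf]
  }
  seeds <- 1:20
  with_scatter <- vapply(seeds, function(s) rmsecv_at(0.05, s), numeric(1))
  without <- vapply(seeds, function(s) rmsecv_at(0, s), numeric(1))
  expect_gt(mean(with_scatter), mean(without))
})
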