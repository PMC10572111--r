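#' Default absorption-band table for the simulator
#'
#' Gaussian bands on the wavenumber axis. The two dominant bands are the
#' water O-H combination/overtone bands near 5100 and 6900 cm^-1 (fresh
#' leaves are roughly three-quarters water, so these swamp everything else).
#' Three price-informative bands sit inside the spectral windows where
#' price-related chemistry shows up (roughly 4378-5130, 6263-6634 and
#' 7386-7757 cm^-1); their concentrations are affine in the sample's price.
#' One decoy band at 5700 cm^-1 varies between samples but carries no price
#' information, so variable-selection stages have something to reject.
#'
#' @return A tibble with columns `center`, `width` (both cm^-1),
#'   `amplitude` (absorbance per concentration unit), `role`
#'   (`"water"`, `"price"`, `"decoy"`), `conc_base`, `conc_per_price`
#'   and `conc_sd`.
#' @export
default_bands <- function() {
  tibble(
    center = c(5100, 6900, 4600, 6450, 7550, 5700),
    width = c(120, 150, 50, 50, 50, 80),
    amplitude = c(1.8, 1.5, 0.25, 0.18, 0.12, 0.2),
    role = c("water", "water", "price", "price", "price", "decoy"),
    conc_base = c(NA, NA, 0, 0, 0, 0.5),
    conc_per_price = c(NA, NA, 1 / 220, 1 / 220, 1 / 220, 0),
    conc_sd = c(NA, NA, 0.02, 0.02, 0.02, 0.15)
  )
}

#' Simulation configuration
#'
#' Defines the study conditions the generator emulates: seven quality
#' grades of eight samples each, quality-index (QI) endpoints 0.552 (grade
#' 1) down to 0.383 (grade 7), purchase prices 220 down to 30 RMB/kg, a
#' 10,000 cm^-1 grid with 3.857 cm^-1 spacing and 1557 points, a 3:1
#' grade-stratified calibration/prediction split, and 14 external market
#' samples with prices drawn uniformly over the price range.
#'
#' @param n_per_grade Samples per grade (7 grades).
#' @param n_external External test samples.
#' @param max_wavenumber,step,n_points Grid parameters, see [nir_grid()].
#' @param qi_endpoints QI at grade 1 and grade 7.
#' @param price_endpoints Price (RMB/kg) at grade 1 and grade 7.
#' @param qi_sd Within-grade QI standard deviation.
#' @param price_jitter_sd Within-grade price standard deviation (RMB/kg).
#' @param humidity_mean,humidity_sd Humidity mass-fraction distribution.
#' @param fiber_endpoints Crude-fiber mass fraction at grades 1 and 7.
#' @param scatter_slope_sd Sd of the per-sample multiplicative scatter slope
#'   (centred on 1).
#' @param scatter_offset_sd Sd of the per-sample additive baseline offset.
#' @param scatter_tilt_sd Sd of the per-sample linear baseline tilt.
#' @param noise_sd Sd of additive i.i.d. absorbance noise per point.
#' @param calibration_ratio Calibration fraction for [split_calibration()].
#' @param bands Band table, see [default_bands()].
#' @param seed Integer seed; all randomness derives from it.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_per_grade = 8,
                       n_external = 14,
                       max_wavenumber = 10000,
                       step = 3.857,
                       n_points = 1557,
                       qi_endpoints = c(0.552, 0.383),
                       price_endpoints = c(220, 30),
                       qi_sd = 0.01,
                       price_jitter_sd = 2,
                       humidity_mean = 0.75,
                       humidity_sd = 0.01,
                       fiber_endpoints = c(0.16, 0.24),
                       scatter_slope_sd = 0.05,
                       scatter_offset_sd = 0.02,
                       scatter_tilt_sd = 0.01,
                       noise_sd = 1e-3,
                       calibration_ratio = 0.75,
                       bands = default_bands(),
                       seed = 1L) {
  cfg <- list(
    n_per_grade = assert_count(n_per_grade, "n_per_grade"),
    n_external = assert_count(n_external, "n_external", min = 0L),
    max_wavenumber = max_wavenumber, step = step,
    n_points = assert_count(n_points, "n_points", min = 2L),
    qi_endpoints = qi_endpoints, price_endpoints = price_endpoints,
    qi_sd = qi_sd, price_jitter_sd = price_jitter_sd,
    humidity_mean = humidity_mean, humidity_sd = humidity_sd,
    fiber_endpoints = fiber_endpoints,
    scatter_slope_sd = scatter_slope_sd,
    scatter_offset_sd = scatter_offset_sd,
    scatter_tilt_sd = scatter_tilt_sd,
    noise_sd = noise_sd,
    calibration_ratio = calibration_ratio,
    bands = as_tibble(bands),
    seed = as.integer(seed)
  )
  if (any(cfg$price_endpoints <= 0) ||
      cfg$price_endpoints[1] <= cfg$price_endpoints[2]) {
    abort("Prices must be positive and decrease from grade 1 to grade 7.")
  }
  if (cfg$noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (any(cfg$bands$width <= 0)) abort("Band widths must be positive.")
  span <- c(max_wavenumber - step * (n_points - 1), max_wavenumber)
  if (any(cfg$bands$center < span[1] | cfg$bands$center > span[2])) {
    abort("All band centers must lie within the grid span.")
  }
  structure(cfg, class = "sim_config")
}

#' Grade targets: noiseless QI and price for a quality grade
#'
#' QI and price are linear in the grade label between the grade-1 and
#' grade-7 endpoints, so at zero noise the grade-QI and grade-price fits
#' are exact.
#'
#' @param grade Integer in 1..7 (vectorised).
#' @param config A [sim_config()].
#' @return A tibble with columns `grade`, `qi`, `price`.
#' @export
grade_targets <- function(grade, config = sim_config()) {
  if (!all(grade %in% 1:7)) abort("`grade` must be in 1..7.")
  f <- (grade - 1) / 6
  tibble(
    grade = as.integer(grade),
    qi = config$qi_endpoints[1] + f * diff(config$qi_endpoints),
    price = config$price_endpoints[1] + f * diff(config$price_endpoints)
  )
}

# price -> noiseless QI, used for external samples with no grade label
price_to_qi <- function(price, config) {
  f <- (price - config$price_endpoints[1]) / diff(config$price_endpoints)
  config$qi_endpoints[1] + f * diff(config$qi_endpoints)
}

#' Draw one sample's constituent profile
#'
#' Humidity is drawn near its mean, crude fiber is linear in grade, and
#' total nitrogen is solved from the quality-index identity
#' `QI = humidity * nitrogen / fiber` at the sample's (noisy) QI, so the
#' identity holds exactly for every generated sample. Band concentrations
#' follow the band table: water bands track humidity, price-informative
#' bands are affine in the sample's price, the decoy is price-blind.
#' Randomness comes from the ambient RNG state; seed upstream.
#'
#' @param grade Integer grade 1..7, or `NA` for an external sample.
#' @param config A [sim_config()].
#' @param price Optional price override (used for external samples).
#' @return A list with `humidity`, `total_nitrogen`, `crude_fiber`, `qi`,
#'   `price` and the numeric vector `band_conc` (one entry per band).
#' @export
generate_constituents <- function(grade, config = sim_config(), price = NULL) {
  if (is.null(price)) {
    tg <- grade_targets(grade, config)
    price <- max(tg$price + rnorm(1, 0, config$price_jitter_sd), 1)
    qi_target <- tg$qi
    f <- (grade - 1) / 6
  } else {
    assert_number(price, "price", positive = TRUE)
    qi_target <- price_to_qi(price, config)
    f <- (price - config$price_endpoints[1]) / diff(config$price_endpoints)
  }
  qi <- qi_target + rnorm(1, 0, config$qi_sd)
  humidity <- config$humidity_mean + rnorm(1, 0, config$humidity_sd)
  fiber <- config$fiber_endpoints[1] + f * diff(config$fiber_endpoints)
  nitrogen <- qi * fiber / humidity
  bands <- config$bands
  conc <- numeric(nrow(bands))
  for (b in seq_len(nrow(bands))) {
    conc[b] <- switch(bands$role[b],
      water = humidity,
      price = bands$conc_base[b] + bands$conc_per_price[b] * price +
        rnorm(1, 0, bands$conc_sd[b]),
      decoy = bands$conc_base[b] + rnorm(1, 0, bands$conc_sd[b]),
      abort(sprintf("Unknown band role '%s'.", bands$role[b]))
    )
  }
  list(humidity = humidity, total_nitrogen = nitrogen, crude_fiber = fiber,
       qi = qi, price = price, band_conc = pmax(conc, 0))
}

#' Render one absorbance spectrum from a constituent profile
#'
#' The clean spectrum is a sum of Gaussian bands weighted by amplitude and
#' concentration; diffuse-reflectance artefacts enter as a per-sample
#' multiplicative slope, additive offset, linear tilt across the axis, and
#' i.i.d. Gaussian noise per point (the distortions SNV/MSC and derivative
#' pretreatments are designed to remove).
#'
#' @param profile Output of [generate_constituents()].
#' @param grid A [nir_grid()].
#' @param bands Band table matching `profile$band_conc`.
#' @param scatter Numeric `c(slope, offset, tilt)`.
#' @param noise_sd Sd of additive absorbance noise (0 for none).
#' @return Numeric absorbance vector of length `grid$n_points`.
#' @export
generate_spectrum <- function(profile, grid, bands = default_bands(),
                              scatter = c(1, 0, 0), noise_sd = 0) {
  validate_grid(grid)
  span <- range(grid$values)
  if (any(bands$center < span[1] | bands$center > span[2])) {
    abort("All band centers must lie within the grid span.")
  }
  if (length(profile$band_conc) != nrow(bands)) {
    abort("`profile$band_conc` length must match the band table.")
  }
  wn <- grid$values
  clean <- numeric(grid$n_points)
  for (b in seq_len(nrow(bands))) {
    clean <- clean + bands$amplitude[b] * profile$band_conc[b] *
      exp(-(wn - bands$center[b])^2 / (2 * bands$width[b]^2))
  }
  tilt_axis <- (seq_len(grid$n_points) - 1) / (grid$n_points - 1)
  out <- scatter[1] * clean + scatter[2] + scatter[3] * tilt_axis
  if (noise_sd > 0) out <- out + rnorm(grid$n_points, 0, noise_sd)
  out
}

#' Generate a full synthetic study dataset
#'
#' Produces `7 * n_per_grade` graded samples split 3:1 into calibration and
#' prediction sets (stratified by grade), plus `n_external` external market
#' samples with uniformly distributed prices. The external block uses a
#' separate seed stream so it cannot leak into the graded draw. The whole
#' dataset is a deterministic function of `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A [spectra_set()]; its sample table carries the extra columns
#'   `humidity`, `total_nitrogen`, `crude_fiber` and `qi`.
#' @export
generate_dataset <- function(config = sim_config()) {
  grid <- nir_grid(config$max_wavenumber, config$step, config$n_points)
  draw_block <- function(grades, prices, ids, seed_tag) {
    with_seed(derive_seed(config$seed, seed_tag), {
      profs <- vector("list", length(ids))
      spectra <- matrix(0, length(ids), grid$n_points)
      for (i in seq_along(ids)) {
        profs[[i]] <- if (is.na(grades[i])) {
          generate_constituents(NA, config, price = prices[i])
        } else {
          generate_constituents(grades[i], config)
        }
        scatter <- c(1 + rnorm(1, 0, config$scatter_slope_sd),
                     rnorm(1, 0, config$scatter_offset_sd),
                     rnorm(1, 0, config$scatter_tilt_sd))
        spectra[i, ] <- generate_spectrum(profs[[i]], grid, config$bands,
                                          scatter, config$noise_sd)
      }
      list(
        spectra = spectra,
        samples = tibble(
          sample_id = ids,
          grade = as.integer(grades),
          price = map_dbl(profs, "price"),
          split = NA_character_,
          humidity = map_dbl(profs, "humidity"),
          total_nitrogen = map_dbl(profs, "total_nitrogen"),
          crude_fiber = map_dbl(profs, "crude_fiber"),
          qi = map_dbl(profs, "qi")
        )
      )
    })
  }

  grades <- rep(1:7, each = config$n_per_grade)
  ids <- sprintf("G%d-%02d", grades, sequence(rep(config$n_per_grade, 7)))
  graded <- draw_block(grades, prices = NULL, ids, "graded")

  if (config$n_external > 0) {
    ext_prices <- with_seed(derive_seed(config$seed, "external-prices"),
      runif(config$n_external,
            min(config$price_endpoints), max(config$price_endpoints)))
    ext <- draw_block(rep(NA_integer_, config$n_external), ext_prices,
                      sprintf("EXT-%02d", seq_len(config$n_external)),
                      "external")
    ext$samples$split <- "external"
    spectra <- rbind(graded$spectra, ext$spectra)
    samples <- bind_rows(graded$samples, ext$samples)
  } else {
    spectra <- graded$spectra
    samples <- graded$samples
  }

  set <- spectra_set(spectra, samples, grid)
  split_calibration(set, config$calibration_ratio,
                    seed = derive_seed(config$seed, "split"))
}
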