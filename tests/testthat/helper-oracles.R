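# Independent oracles and fixture builders shared across the suite.

# Moore-Penrose pseudoinverse via SVD (least-squares oracle).
pinv <- function(A, tol = 1e-10) {
  s <- svd(A)
  keep <- s$d > tol * s$d[1]
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

# Closed-form simple linear regression y ~ x (normal equations).
ols_simple <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  c(intercept = a, slope = b)
}

# SVD-route PLS1: identical model to NIPALS for a single response, computed
# without deflation-by-scores — each weight is the dominant singular vector
# of the deflated cross-covariance; deflation uses explicit projection.
svd_pls1 <- function(X, y, n_factors) {
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2, x_mean)
  yc <- y - y_mean
  p <- ncol(X)
  W <- matrix(0, p, n_factors)
  P <- matrix(0, p, n_factors)
  q <- numeric(n_factors)
  for (a in seq_len(n_factors)) {
    s <- svd(matrix(crossprod(Xc, yc), ncol = 1), nu = 1, nv = 0)
    w <- s$u[, 1] * sign(sum(s$u[, 1] * crossprod(Xc, yc)))
    t_sc <- Xc %*% w
    tt <- sum(t_sc^2)
    P[, a] <- crossprod(Xc, t_sc) / tt
    q[a] <- sum(yc * t_sc) / tt
    W[, a] <- w
    Xc <- Xc - t_sc %*% t(P[, a])
    yc <- yc - q[a] * t_sc
  }
  B <- W %*% solve(crossprod(P, W), q)
  list(x_mean = x_mean, y_mean = y_mean, coef = drop(B))
}

# Brute-force Savitzky-Golay oracle: at every point fit a polynomial by
# least squares on the window (one-sided at the edges) and differentiate.
sg_oracle <- function(x, order, window, polyorder) {
  n <- length(x)
  h <- (window - 1) %/% 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    idx <- if (i <= h) {
      1:window
    } else if (i > n - h) {
      (n - window + 1):n
    } else {
      (i - h):(i + h)
    }
    d <- idx - i
    fit <- lm(x[idx] ~ poly(d, polyorder, raw = TRUE))
    cf <- coef(fit)
    out[i] <- if (order == 1) cf[2] else 2 * cf[3]
  }
  out
}

# Random valid spectra set (metadata restricted to the canonical columns).
random_spectra_set <- function(n = 6, p = 9, seed = 1) {
  withr::with_seed(seed, {
    grid <- nir_grid(8000, 12.5, p)
    mat <- matrix(rnorm(n * p), n, p)
    samples <- tibble::tibble(
      sample_id = sprintf("S%02d", seq_len(n)),
      grade = sample(c(1:7, NA), n, replace = TRUE),
      price = ifelse(runif(n) < 0.8, runif(n, 30, 220), NA),
      split = sample(c("calibration", "prediction", "external", NA),
                     n, replace = TRUE)
    )
    spectra_set(mat, samples, grid)
  })
}

# Reduced-axis simulation config: same 10,000 -> ~4,000 cm^-1 span and band
# chemistry, coarser sampling, for fast tests.
fast_cfg <- function(..., n_points = 156, step = 38.6) {
  sim_config(..., n_points = n_points, step = step)
}

# Reduced-scale pipeline configuration for end-to-end tests: coarser axis,
# narrower si-PLS scan bracketing the 16-interval optimum, smaller GA and
# network budgets, prediction-set metrics only.
fast_pipeline_cfg <- function(seed) {
  pipeline_config(
    data = fast_cfg(),
    sipls_interval_counts = 14:18,
    sipls_combo_size = 4,
    ga = list(population_size = 32, n_generations = 30),
    ann = list(cv_epochs = 200),
    ann_cv = FALSE,
    seed = seed
  )
}
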