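#' Fit a PLS1 calibration by NIPALS
#'
#' Single-response partial least squares on column-centered `X` and
#' centered `y`. Deterministic: NIPALS for one response needs no iteration
#' or random start, each factor being extracted in closed form. Regression
#' vectors are stored for every factor truncation `1..n_factors`, so a
#' single fit serves all model sizes.
#'
#' @param X Numeric matrix, samples in rows.
#' @param y Numeric response vector (prices, RMB/kg).
#' @param n_factors Number of latent factors,
#'   `1 <= n_factors <= min(n - 1, ncol(X))`.
#' @return An object of class `pls_model` with elements `x_mean`, `y_mean`,
#'   `weights`, `loadings`, `q` (inner regression coefficients),
#'   `coefficients` (`ncol(X) x n_factors`, one regression vector per
#'   truncation) and `n_factors` (may be fewer than requested if `X`
#'   deflates to zero first).
#' @export
fit_pls <- function(X, y, n_factors) {
  if (!is.matrix(X)) X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) abort("`y` length must match rows of `X`.")
  if (anyNA(X) || anyNA(y)) abort("Missing values are not allowed.")
  if (var(y) == 0) abort("`y` has zero variance.")
  n_factors <- assert_count(n_factors, "n_factors")
  cap <- min(n - 1L, p)
  if (n_factors > cap) {
    abort(sprintf("`n_factors` must be <= min(n - 1, p) = %d.", cap))
  }
  core <- nipals_pls1(X, as.numeric(y), n_factors)
  structure(
    list(x_mean = drop(core$x_mean), y_mean = core$y_mean,
         weights = core$weights, loadings = core$loadings,
         q = drop(core$q), coefficients = core$coefficients,
         n_factors = as.integer(core$n_factors), n_samples = n),
    class = "pls_model"
  )
}

#' Predict prices from a PLS calibration
#'
#' `y_mean + (X - x_mean) %*% b` with the regression vector of the
#' requested truncation.
#'
#' @param object A `pls_model`.
#' @param newdata Numeric matrix with `ncol(X)` columns (or a vector).
#' @param n_factors Truncation to use (default: all fitted factors).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.pls_model <- function(object, newdata, n_factors = object$n_factors,
                              ...) {
  if (!is.matrix(newdata)) newdata <- matrix(newdata, nrow = 1)
  if (ncol(newdata) != length(object$x_mean)) {
    abort(sprintf("`newdata` has %d columns; the model expects %d.",
                  ncol(newdata), length(object$x_mean)))
  }
  n_factors <- assert_count(n_factors, "n_factors")
  if (n_factors > object$n_factors) {
    abort("`n_factors` exceeds the fitted number of factors.")
  }
  b <- object$coefficients[, n_factors]
  drop(object$y_mean + sweep(newdata, 2, object$x_mean) %*% b)
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d factor(s), %d variables, n = %d\n",
              x$n_factors, nrow(x$coefficients), x$n_samples))
  invisible(x)
}

#' Regression vector of a PLS model as a tibble
#' @param x A fitted `pls_model`.
#' @param ... Unused.
#' @return A tibble with columns `variable` and `coefficient`.
#' @method tidy pls_model
#' @export
tidy.pls_model <- function(x, ...) {
  tibble(
    variable = seq_len(nrow(x$coefficients)),
    coefficient = x$coefficients[, x$n_factors]
  )
}

#' Cross-validation scheme descriptors
#'
#' `cv_loo()` is leave-one-out (deterministic); `cv_kfold()` is seeded
#' k-fold. The package default is leave-one-out for the small calibration
#' sets typical here (`n <= 60`) and 5-fold otherwise, available as
#' `cv_default(n)`.
#'
#' @param k Number of folds.
#' @param seed Integer seed for the fold assignment.
#' @param n Sample count (for `cv_default`).
#' @return A list of class `cv_scheme`.
#' @export
cv_loo <- function() structure(list(type = "loo"), class = "cv_scheme")

#' @rdname cv_loo
#' @export
cv_kfold <- function(k = 5, seed = 1L) {
  k <- assert_count(k, "k", min = 2L)
  structure(list(type = "kfold", k = k, seed = as.integer(seed)),
            class = "cv_scheme")
}

#' @rdname cv_loo
#' @export
cv_default <- function(n) if (n <= 60) cv_loo() else cv_kfold(5)

cv_folds <- function(scheme, n) {
  if (!inherits(scheme, "cv_scheme")) abort("`scheme` must be a cv_scheme.")
  if (scheme$type == "loo") return(seq_len(n))
  if (scheme$k > n) abort("`k` must not exceed the number of samples.")
  with_seed(scheme$seed, sample(rep(seq_len(scheme$k), length.out = n)))
}

# Held-out predictions for every factor truncation 1..max_factors.
# Returns an n x max_factors matrix (columns = factor counts); factor
# counts that are infeasible in some fold reuse that fold's largest
# feasible truncation.
cv_predictions <- function(X, y, max_factors, scheme = cv_default(nrow(X))) {
  if (!is.matrix(X)) X <- as.matrix(X)
  n <- nrow(X)
  folds <- cv_folds(scheme, n)
  max_factors <- assert_count(max_factors, "max_factors")
  if (anyNA(X) || anyNA(y)) abort("Missing values are not allowed.")
  pls_cv_preds(X, as.numeric(y), max_factors, as.integer(folds))
}

#' Cross-validate a PLS calibration
#'
#' Every held-out sample is predicted by a model fit without it; RMSECV is
#' the root mean square of those held-out residuals and R^2cv the
#' corresponding coefficient of determination.
#'
#' @param X Numeric matrix.
#' @param y Response vector.
#' @param n_factors Number of PLS factors.
#' @param scheme A [cv_loo()] or [cv_kfold()] scheme.
#' @return A tibble with one row: `n`, `n_factors`, `rmsecv`, `r2cv`.
#' @export
cross_validate <- function(X, y, n_factors, scheme = cv_default(nrow(X))) {
  preds <- cv_predictions(X, y, n_factors, scheme)[, n_factors]
  tibble(n = length(y), n_factors = as.integer(n_factors),
         rmsecv = rmse(y, preds), r2cv = r_squared(y, preds))
}

#' Choose the PLS factor count by cross-validation
#'
#' Returns the factor count in `1..max_factors` minimizing RMSECV, with
#' ties broken toward fewer factors.
#'
#' @inheritParams cross_validate
#' @param max_factors Largest factor count to consider.
#' @return Integer factor count, with the per-count RMSECV trace attached
#'   as attribute `"trace"` (a tibble).
#' @export
select_factors <- function(X, y, max_factors = 10,
                           scheme = cv_default(nrow(X))) {
  if (!is.matrix(X)) X <- as.matrix(X)
  max_factors <- min(assert_count(max_factors, "max_factors"),
                     nrow(X) - 1L, ncol(X))
  preds <- cv_predictions(X, y, max_factors, scheme)
  trace <- map_dbl(seq_len(max_factors), function(a) rmse(y, preds[, a]))
  best <- which.min(trace) # first minimum = fewest factors on ties
  structure(as.integer(best),
            trace = tibble(n_factors = seq_len(max_factors), rmsecv = trace))
}

# Lean RMSECV trace for hot search loops: fixed fold labels, no tibbles.
# Returns the per-factor-count RMSECV vector (length max_factors).
cv_trace_lean <- function(X, y, max_factors, folds) {
  preds <- pls_cv_preds(X, as.numeric(y), as.integer(max_factors),
                        as.integer(folds))
  sqrt(colMeans((preds - y)^2))
}
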