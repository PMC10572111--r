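#' Principal component analysis of selected spectral points
#'
#' Covariance PCA on mean-centered, unscaled absorbance (columns share
#' units, so no correlation scaling). Components are ordered by decreasing
#' variance; each component's sign is fixed so its largest-magnitude
#' loading element is positive, making scores reproducible.
#'
#' @param X Numeric matrix, samples in rows (`n >= 2`).
#' @return An object of class `pca_model`: `mean`, `loadings` (orthonormal
#'   columns), `explained` (variances), `contribution` (percent per
#'   component, summing to 100), `scores` (training scores) and
#'   `n_components`.
#' @export
fit_pca <- function(X) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (nrow(X) < 2) abort("PCA needs at least two samples.")
  if (anyNA(X)) abort("Missing values are not allowed.")
  fit <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  load <- fit$rotation
  scores <- fit$x
  for (j in seq_len(ncol(load))) {
    i_max <- which.max(abs(load[, j]))
    if (load[i_max, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  vars <- fit$sdev^2
  structure(
    list(mean = fit$center, loadings = load, explained = vars,
         contribution = 100 * vars / sum(vars), scores = scores,
         n_components = length(vars)),
    class = "pca_model"
  )
}

#' @export
print.pca_model <- function(x, ...) {
  k <- min(3L, x$n_components)
  cat(sprintf("<pca_model> %d components; first %d explain %.3f%%\n",
              x$n_components, k, sum(x$contribution[1:k])))
  invisible(x)
}

#' Project data onto principal components
#'
#' `(X - mean) %*% loadings`, truncated to the first `k` components.
#'
#' @param model A `pca_model`.
#' @param X Numeric matrix (or vector) with the training dimensionality.
#' @param k Number of components to keep.
#' @return An `n x k` score matrix.
#' @export
pca_transform <- function(model, X, k = model$n_components) {
  stopifnot(inherits(model, "pca_model"))
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  if (ncol(X) != length(model$mean)) {
    abort(sprintf("`X` has %d columns; the model expects %d.",
                  ncol(X), length(model$mean)))
  }
  k <- assert_count(k, "k")
  if (k > model$n_components) {
    abort("`k` exceeds the number of components.")
  }
  sweep(X, 2, model$mean) %*% model$loadings[, seq_len(k), drop = FALSE]
}

#' Cumulative contribution rates
#'
#' Running sums of the per-component percent contributions, the usual
#' "PC(1-k)" table.
#'
#' @param model A `pca_model`.
#' @param k_max How many leading components to accumulate.
#' @return Numeric vector of length `k_max`, non-decreasing, ending at
#'   most at 100.
#' @export
cumulative_contributions <- function(model, k_max = model$n_components) {
  stopifnot(inherits(model, "pca_model"))
  k_max <- assert_count(k_max, "k_max")
  if (k_max > model$n_components) {
    abort("`k_max` exceeds the number of components.")
  }
  cumsum(model$contribution[seq_len(k_max)])
}

#' Per-component PCA summary
#' @param x A `pca_model`.
#' @param ... Unused.
#' @return A tibble with `component`, `variance`, `contribution` and
#'   `cumulative` (both in percent).
#' @method tidy pca_model
#' @export
tidy.pca_model <- function(x, ...) {
  tibble(
    component = seq_len(x$n_components),
    variance = x$explained,
    contribution = x$contribution,
    cumulative = cumsum(x$contribution)
  )
}

#' Score plot of the first two principal components
#' @param object A `pca_model`.
#' @param colour Optional vector (length n) to colour points by, e.g.
#'   price or grade.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pca_model
#' @export
autoplot.pca_model <- function(object, colour = NULL, ...) {
  df <- tibble(score1 = object$scores[, 1],
               score2 = if (object$n_components >= 2) {
                 object$scores[, 2]
               } else {
                 0
               })
  p <- if (is.null(colour)) {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$score1, y = .data$score2))
  } else {
    df$colour <- colour
    ggplot2::ggplot(df, ggplot2::aes(x = .data$score1, y = .data$score2,
                                     colour = .data$colour))
  }
  p + ggplot2::geom_point() +
    ggplot2::labs(x = sprintf("PC1 (%.2f%%)", object$contribution[1]),
                  y = sprintf("PC2 (%.2f%%)",
                              if (object$n_components >= 2) {
                                object$contribution[2]
                              } else {
                                0
                              }),
                  title = "PCA score plot") +
    ggplot2::theme_minimal()
}
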