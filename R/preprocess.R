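#' Standard normal variate transform
#'
#' Centers each spectrum to mean zero and scales it to unit sample standard
#' deviation (n-1 denominator), removing per-sample multiplicative and
#' additive scatter.
#'
#' @param x Numeric vector (one spectrum) or matrix (rows = spectra).
#' @return Transformed vector or matrix of the same shape.
#' @export
snv <- function(x) {
  if (is.matrix(x)) {
    out <- t(apply(x, 1, snv))
    dimnames(out) <- dimnames(x)
    return(out)
  }
  if (length(x) < 2) abort("SNV needs at least two points.")
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    abort("SNV is undefined for a constant spectrum.")
  }
  (x - mean(x)) / s
}

#' Multiplicative scatter correction
#'
#' Regresses each spectrum on a reference spectrum by ordinary least
#' squares, `x ~ a * ref + b`, and returns `(x - b) / a`, removing the
#' per-sample affine scatter component.
#'
#' @param x Numeric matrix (rows = spectra).
#' @param reference `"mean"` (column means of `x`) or a numeric vector.
#' @return Corrected matrix of the same shape.
#' @export
msc <- function(x, reference = "mean") {
  if (!is.matrix(x)) abort("`x` must be a matrix with spectra in rows.")
  if (identical(reference, "mean")) {
    if (nrow(x) < 2) abort("MSC with a mean reference needs >= 2 spectra.")
    reference <- colMeans(x)
  }
  if (length(reference) != ncol(x)) {
    abort("`reference` length must match the number of points.")
  }
  v <- sum((reference - mean(reference))^2)
  if (v == 0) abort("MSC reference has zero variance.")
  rc <- reference - mean(reference)
  out <- x
  for (i in seq_len(nrow(x))) {
    a <- sum((x[i, ] - mean(x[i, ])) * rc) / v
    if (a == 0) abort(sprintf("MSC slope is zero for spectrum %d.", i))
    b <- mean(x[i, ]) - a * mean(reference)
    out[i, ] <- (x[i, ] - b) / a
  }
  out
}

# Savitzky-Golay filter weights: fit a polynomial of degree `polyorder` to
# the window offsets `d`, return the linear functional giving the
# `order`-th derivative evaluated at offset `d0`.
sg_weights <- function(d, polyorder, order, d0) {
  A <- outer(d, 0:polyorder, "^")
  v <- numeric(polyorder + 1)
  for (j in order:polyorder) {
    v[j + 1] <- factorial(j) / factorial(j - order) * d0^(j - order)
  }
  drop(v %*% solve(crossprod(A), t(A)))
}

#' Savitzky-Golay derivative with respect to point index
#'
#' Local polynomial least-squares derivative. Interior points use a
#' centered window; the first and last half-windows are handled by fitting
#' the polynomial on the one-sided edge window and evaluating its
#' derivative at each edge point, so output dimensions equal input
#' dimensions.
#'
#' @param x Numeric vector or matrix (rows = spectra).
#' @param order Derivative order, 1 or 2.
#' @param window Odd window length, `>= 5`, `<= n_points`.
#' @param polyorder Polynomial degree, `order <= polyorder < window`.
#' @return Derivative of the same shape as `x`.
#' @export
sg_derivative <- function(x, order, window = 11, polyorder = 2) {
  if (!order %in% c(1, 2)) abort("`order` must be 1 or 2.")
  window <- assert_count(window, "window", min = 5L)
  if (window %% 2 == 0) abort("`window` must be odd.")
  polyorder <- assert_count(polyorder, "polyorder", min = as.integer(order))
  if (polyorder >= window) abort("`polyorder` must be < `window`.")
  vec_in <- !is.matrix(x)
  if (vec_in) x <- matrix(x, nrow = 1)
  n <- ncol(x)
  if (window > n) abort("`window` must not exceed the number of points.")
  h <- (window - 1L) %/% 2L

  w_int <- sg_weights(-h:h, polyorder, order, 0)
  out <- x * 0
  # interior: sliding dot product via the embed trick (embed reverses order)
  interior_cols <- (h + 1L):(n - h)
  for (i in seq_len(nrow(x))) {
    E <- embed(x[i, ], window) # row t = x[t+window-1], ..., x[t]
    out[i, interior_cols] <- E %*% rev(w_int)
  }
  # edges: polynomial fit on the one-sided window, derivative at the point
  for (p in seq_len(h)) {
    w_head <- sg_weights(0:(window - 1L), polyorder, order, p - 1L)
    w_tail <- sg_weights(0:(window - 1L), polyorder, order, h + p)
    out[, p] <- x[, 1:window, drop = FALSE] %*% w_head
    out[, n - h + p] <- x[, (n - window + 1L):n, drop = FALSE] %*% w_tail
  }
  if (vec_in) out <- drop(out)
  out
}

#' Define a pretreatment recipe
#'
#' An ordered list of steps from `{"snv", "msc", "fd", "sd"}`, at most one
#' scatter correction (snv/msc) and at most one derivative (fd/sd). The
#' empty recipe is the identity ("none").
#'
#' @param steps Character vector of steps, possibly empty.
#' @param window,polyorder Savitzky-Golay parameters for fd/sd.
#' @return An object of class `pretreat_spec`.
#' @examples
#' pretreat_spec(c("snv", "sd"))
#' @export
pretreat_spec <- function(steps = character(), window = 11, polyorder = 2) {
  steps <- tolower(steps)
  bad <- setdiff(steps, c("snv", "msc", "fd", "sd"))
  if (length(bad)) {
    abort(paste0("Unknown pretreatment step(s): ",
                 paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(steps)) abort("Pretreatment steps must be distinct.")
  if (sum(steps %in% c("snv", "msc")) > 1) {
    abort("At most one scatter correction (snv or msc).")
  }
  if (sum(steps %in% c("fd", "sd")) > 1) {
    abort("At most one derivative (fd or sd).")
  }
  window <- assert_count(window, "window", min = 5L)
  if (window %% 2 == 0) abort("`window` must be odd.")
  polyorder <- assert_count(polyorder, "polyorder", min = 1L)
  if (polyorder >= window) abort("`polyorder` must be < `window`.")
  structure(list(steps = steps, window = window, polyorder = polyorder),
            class = "pretreat_spec")
}

#' @export
print.pretreat_spec <- function(x, ...) {
  cat("<pretreat_spec>", pretreat_label(x), "\n")
  invisible(x)
}

#' Human-readable label for a pretreatment recipe
#' @param spec A [pretreat_spec()].
#' @return A string such as `"snv+sd"` or `"none"`.
#' @export
pretreat_label <- function(spec) {
  if (length(spec$steps) == 0) "none" else paste(spec$steps, collapse = "+")
}

#' Apply a pretreatment recipe to a spectra set
#'
#' Steps are applied in the listed order (scatter correction before
#' derivative for the named combinations). Sample metadata and the grid are
#' untouched.
#'
#' @param set A [spectra_set()] (or a bare absorbance matrix).
#' @param spec A [pretreat_spec()].
#' @return Object of the same type as `set` with transformed absorbances.
#' @export
apply_pretreatment <- function(set, spec) {
  if (!inherits(spec, "pretreat_spec")) {
    abort("`spec` must be a `pretreat_spec`.")
  }
  mat <- if (is_spectra_set(set)) set$absorbance else set
  for (step in spec$steps) {
    mat <- switch(step,
      snv = snv(mat),
      msc = msc(mat),
      fd = sg_derivative(mat, 1, spec$window, spec$polyorder),
      sd = sg_derivative(mat, 2, spec$window, max(spec$polyorder, 2L))
    )
  }
  if (is_spectra_set(set)) {
    spectra_set(mat, set$samples, set$grid)
  } else {
    mat
  }
}

#' The nine-recipe pretreatment catalogue
#'
#' The standard comparison set: raw spectra, each single method, and the
#' scatter-correction-first combinations.
#'
#' @param window,polyorder Savitzky-Golay parameters passed to each recipe.
#' @return Named list of nine [pretreat_spec()] objects: none, snv, fd, sd,
#'   msc, snv+fd, snv+sd, msc+fd, msc+sd.
#' @export
pretreatment_catalogue <- function(window = 11, polyorder = 2) {
  specs <- list(
    character(), "snv", "fd", "sd", "msc",
    c("snv", "fd"), c("snv", "sd"), c("msc", "fd"), c("msc", "sd")
  )
  out <- lapply(specs, pretreat_spec, window = window, polyorder = polyorder)
  names(out) <- vapply(out, pretreat_label, character(1))
  out
}
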