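#' Synergy-interval PLS search
#'
#' For each interval count `k`, partitions the spectral axis into `k`
#' near-equal contiguous intervals ([partition_intervals()]) and evaluates
#' every combination of `combo_size` intervals by cross-validated PLS on
#' the concatenated columns, choosing the factor count per combination via
#' [select_factors()]. The enumeration is exhaustive (no pruning). The
#' global winner is the (k, combination, factor count) with the lowest
#' RMSECV; ties break toward smaller `k`, then the lexicographically
#' smaller combination.
#'
#' @param X Calibration absorbance matrix (columns in descending
#'   wavenumber order, matching `grid`).
#' @param y Calibration prices (RMB/kg).
#' @param grid A [nir_grid()] with `n_points == ncol(X)`.
#' @param interval_counts Integer vector of interval counts to scan
#'   (default `10:25`).
#' @param combo_size Number of intervals per combination (2, 3 or 4).
#' @param max_factors Factor-count cap for [select_factors()].
#' @param scheme Cross-validation scheme.
#'
#' @return An object of class `sipls_result` with `table` (per-k best rows:
#'   `n_intervals`, `n_factors`, `combo` list-column, `rmsecv`), `best`
#'   (the winning row plus its wavenumber ranges), `combo_size` and
#'   `scheme`.
#' @export
sipls_search <- function(X, y, grid, interval_counts = 10:25,
                         combo_size = 4, max_factors = 10,
                         scheme = cv_default(nrow(X))) {
  if (!is.matrix(X)) X <- as.matrix(X)
  validate_grid(grid)
  if (ncol(X) != grid$n_points) {
    abort("`X` columns must match `grid$n_points`.")
  }
  combo_size <- assert_count(combo_size, "combo_size", min = 1L)
  interval_counts <- sort(unique(as.integer(interval_counts)))
  if (any(interval_counts < 2) || any(interval_counts > grid$n_points)) {
    abort("`interval_counts` must lie in [2, n_points].")
  }

  folds <- cv_folds(scheme, nrow(X))
  rows <- list()
  for (k in interval_counts) {
    if (combo_size > k) {
      warn(sprintf("combo_size %d > %d intervals; skipping k = %d.",
                   combo_size, k, k))
      next
    }
    part <- partition_intervals(grid$n_points, k)
    blocks <- lapply(seq_len(k), function(i) {
      interval_columns(part, i, grid$n_points)
    })
    combos <- combn(k, combo_size)
    best_k <- NULL
    for (j in seq_len(ncol(combos))) {
      combo <- combos[, j]
      cols <- sort(unlist(blocks[combo]))
      trace <- cv_trace_lean(X[, cols, drop = FALSE], y,
                             min(max_factors, length(cols), nrow(X) - 1L),
                             folds)
      nf <- which.min(trace) # first minimum = fewest factors on ties
      if (is.null(best_k) || trace[nf] < best_k$rmsecv) {
        best_k <- list(combo = combo, n_factors = as.integer(nf),
                       rmsecv = trace[nf])
      }
    }
    rows[[length(rows) + 1L]] <- tibble(
      n_intervals = k,
      n_factors = best_k$n_factors,
      combo = list(best_k$combo),
      rmsecv = best_k$rmsecv
    )
  }
  if (length(rows) == 0) abort("No interval count could be evaluated.")
  table <- bind_rows(rows)
  ibest <- which.min(table$rmsecv) # ascending k order => smaller k on ties
  best <- as.list(table[ibest, ])
  best$combo <- best$combo[[1]]
  best$wavenumbers <- intervals_to_wavenumbers(
    partition_intervals(grid$n_points, best$n_intervals), best$combo, grid)

  structure(
    list(table = table, best = best, combo_size = combo_size,
         scheme = scheme, grid = grid),
    class = "sipls_result"
  )
}

#' @export
print.sipls_result <- function(x, ...) {
  cat(sprintf(
    "<sipls_result> best: %d intervals, combo [%s], %d factors, RMSECV %.3f\n",
    x$best$n_intervals, paste(x$best$combo, collapse = " "),
    x$best$n_factors, x$best$rmsecv))
  invisible(x)
}

#' Per-interval-count summary of an si-PLS search
#' @param x A `sipls_result`.
#' @param ... Unused.
#' @return A tibble with one row per interval count: `n_intervals`,
#'   `n_factors`, `combo` (printed form), `rmsecv`.
#' @method tidy sipls_result
#' @export
tidy.sipls_result <- function(x, ...) {
  x$table |>
    mutate(combo = map(.data$combo, function(cc) {
      paste0("[", paste(cc, collapse = " "), "]")
    }) |> unlist())
}

#' One-row summary of the winning si-PLS model
#' @param x A `sipls_result`.
#' @param ... Unused.
#' @return A one-row tibble: `n_intervals`, `n_factors`, `combo`, `rmsecv`,
#'   `n_points` (columns in the winning combination).
#' @method glance sipls_result
#' @export
glance.sipls_result <- function(x, ...) {
  tibble(
    n_intervals = x$best$n_intervals,
    n_factors = x$best$n_factors,
    combo = paste0("[", paste(x$best$combo, collapse = " "), "]"),
    rmsecv = x$best$rmsecv,
    n_points = sum(x$best$wavenumbers$size)
  )
}

#' Matrix columns selected by the winning si-PLS combination
#' @param result A `sipls_result`.
#' @return Sorted integer column indices into the original matrix.
#' @export
sipls_columns <- function(result) {
  stopifnot(inherits(result, "sipls_result"))
  part <- partition_intervals(result$grid$n_points, result$best$n_intervals)
  interval_columns(part, result$best$combo, result$grid$n_points)
}

#' RMSECV trace of an si-PLS search
#'
#' Best cross-validated error per interval count, the shape of the
#' interval-count scan table.
#'
#' @param object A `sipls_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sipls_result
#' @export
autoplot.sipls_result <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = .data$n_intervals, y = .data$rmsecv)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = object$table[which.min(object$table$rmsecv), ],
                        colour = "red", size = 3) +
    ggplot2::labs(x = "Number of intervals",
                  y = "RMSECV (RMB/kg)",
                  title = "si-PLS interval-count scan") +
    ggplot2::theme_minimal()
}
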