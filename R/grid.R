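#' Construct a wavenumber grid
#'
#' Builds the shared spectral axis as an arithmetic sequence of wavenumbers,
#' descending from `max_wavenumber` (FT-NIR acquisition order, e.g. 10,000
#' down towards 4,000 cm^-1). The low end is emergent from
#' `(max_wavenumber, step, n_points)` rather than specified, because
#' instrument grids are defined by their start and spacing.
#'
#' @param max_wavenumber Highest wavenumber on the axis (cm^-1).
#' @param step Spacing between adjacent points (cm^-1), positive.
#' @param n_points Number of grid points (>= 2).
#'
#' @return An object of class `nir_grid`: a list with `values` (descending
#'   wavenumbers), `step`, and `n_points`.
#' @examples
#' g <- nir_grid(10000, 3.857, 1557)
#' range(g$values)
#' @export
nir_grid <- function(max_wavenumber, step, n_points) {
  assert_number(max_wavenumber, "max_wavenumber", positive = TRUE)
  assert_number(step, "step", positive = TRUE)
  n_points <- assert_count(n_points, "n_points", min = 2L)
  structure(
    list(
      values = max_wavenumber - step * (seq_len(n_points) - 1),
      step = step,
      n_points = n_points
    ),
    class = "nir_grid"
  )
}

#' @export
print.nir_grid <- function(x, ...) {
  cat(sprintf(
    "<nir_grid> %d points, %.4f to %.4f cm^-1, step %.4g cm^-1\n",
    x$n_points, x$values[1], x$values[x$n_points], x$step
  ))
  invisible(x)
}

is_nir_grid <- function(x) inherits(x, "nir_grid")

validate_grid <- function(grid) {
  if (!is_nir_grid(grid)) abort("`grid` must be a `nir_grid` object.")
  d <- diff(grid$values)
  if (any(d >= 0)) abort("Grid must be strictly descending.")
  if (any(abs(d + grid$step) > 1e-9 * abs(grid$step))) {
    abort("Grid spacing is not constant.")
  }
  invisible(grid)
}

#' Partition grid points into near-equal contiguous intervals
#'
#' Splits `n_points` spectral points into `k` contiguous intervals whose
#' sizes differ by at most one. With `n_points = k * q + r`, the first `r`
#' intervals (lowest labels) receive `q + 1` points. Positions are 1-based
#' and ordered by ascending wavenumber, so interval 1 sits at the
#' low-wavenumber end of the axis; use [interval_columns()] to translate a
#' label into columns of a spectra matrix (which are stored in descending
#' wavenumber order).
#'
#' @param n_points Total number of grid points.
#' @param k Number of intervals, `1 <= k <= n_points`.
#'
#' @return A tibble with columns `interval` (1-based label), `start`, `end`
#'   (inclusive positions in ascending-wavenumber order) and `size`.
#' @examples
#' partition_intervals(10, 2)
#' sum(partition_intervals(1557, 16)$size[c(2, 3, 7, 10)]) # 390
#' @export
partition_intervals <- function(n_points, k) {
  n_points <- assert_count(n_points, "n_points")
  k <- assert_count(k, "k")
  if (k > n_points) abort("`k` must not exceed `n_points`.")
  q <- n_points %/% k
  r <- n_points %% k
  sizes <- rep(q, k) + c(rep(1L, r), rep(0L, k - r))
  ends <- cumsum(sizes)
  tibble(
    interval = seq_len(k),
    start = ends - sizes + 1L,
    end = ends,
    size = as.integer(sizes)
  )
}

#' Matrix columns covered by selected intervals
#'
#' Maps interval labels from [partition_intervals()] to column indices of an
#' absorbance matrix whose columns follow the descending wavenumber grid.
#'
#' @param partition Tibble from [partition_intervals()].
#' @param combo Integer vector of interval labels.
#' @param n_points Number of grid points (matrix columns).
#'
#' @return Sorted integer vector of column indices.
#' @export
interval_columns <- function(partition, combo, n_points) {
  check_combo(partition, combo)
  cols <- unlist(lapply(combo, function(i) {
    row <- partition[partition$interval == i, ]
    (n_points + 1L - row$end):(n_points + 1L - row$start)
  }))
  sort(unique(cols))
}

check_combo <- function(partition, combo) {
  if (length(combo) == 0 || anyDuplicated(combo) ||
      !all(combo %in% partition$interval)) {
    abort("`combo` must be distinct interval labels present in `partition`.")
  }
  invisible(combo)
}

#' Wavenumber ranges of selected intervals
#'
#' @param partition Tibble from [partition_intervals()].
#' @param combo Integer vector of interval labels.
#' @param grid A `nir_grid` whose `n_points` matches the partition.
#'
#' @return A tibble with columns `interval`, `wn_low`, `wn_high`, `size`.
#' @examples
#' g <- nir_grid(10000, 3.857, 1557)
#' p <- partition_intervals(1557, 16)
#' intervals_to_wavenumbers(p, c(2, 3, 7, 10), g)
#' @export
intervals_to_wavenumbers <- function(partition, combo, grid) {
  validate_grid(grid)
  if (max(partition$end) != grid$n_points) {
    abort("`partition` does not cover this grid.")
  }
  check_combo(partition, combo)
  asc <- rev(grid$values)
  purrr::map_dfr(sort(combo), function(i) {
    row <- partition[partition$interval == i, ]
    pts <- asc[row$start:row$end]
    tibble(interval = i, wn_low = min(pts), wn_high = max(pts),
           size = row$size)
  })
}
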