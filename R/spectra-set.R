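#' Bundle an absorbance matrix with its grid and sample table
#'
#' The central data container: a numeric absorbance matrix (rows = samples,
#' columns = wavenumber points in descending order), the shared
#' [nir_grid()], and a per-sample metadata tibble.
#'
#' @param absorbance Numeric matrix, `n_samples x grid$n_points`, finite.
#' @param samples Data frame with columns `sample_id` (unique), `grade`
#'   (integer 1..7 or `NA`), `price` (RMB/kg, positive or `NA`) and `split`
#'   (`"calibration"`, `"prediction"`, `"external"` or `NA`).
#' @param grid A `nir_grid`.
#'
#' @return An object of class `spectra_set`.
#' @export
spectra_set <- function(absorbance, samples, grid) {
  validate_grid(grid)
  if (!is.matrix(absorbance) || !is.numeric(absorbance)) {
    abort("`absorbance` must be a numeric matrix.")
  }
  samples <- as_tibble(samples)
  required <- c("sample_id", "grade", "price", "split")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols)) {
    abort(paste0("`samples` is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(samples) == 0) abort("`samples` must contain at least one sample.")
  if (nrow(samples) != nrow(absorbance)) {
    abort("`samples` rows must match `absorbance` rows.")
  }
  if (ncol(absorbance) != grid$n_points) {
    abort(sprintf("`absorbance` has %d columns but the grid has %d points.",
                  ncol(absorbance), grid$n_points))
  }
  if (!all(is.finite(absorbance))) {
    bad <- which(!is.finite(absorbance), arr.ind = TRUE)[1, ]
    abort(sprintf("Non-finite absorbance at row %d, column %d.",
                  bad[1], bad[2]))
  }
  if (anyDuplicated(samples$sample_id)) {
    dup <- samples$sample_id[duplicated(samples$sample_id)][1]
    abort(sprintf("Duplicate sample_id: '%s'.", dup))
  }
  ok_grade <- is.na(samples$grade) | samples$grade %in% 1:7
  if (!all(ok_grade)) abort("`grade` must be in 1..7 or NA.")
  ok_price <- is.na(samples$price) | samples$price > 0
  if (!all(ok_price)) abort("`price` must be positive or NA.")
  ok_split <- is.na(samples$split) |
    samples$split %in% c("calibration", "prediction", "external")
  if (!all(ok_split)) {
    abort("`split` must be calibration/prediction/external or NA.")
  }
  rownames(absorbance) <- samples$sample_id
  structure(
    list(grid = grid, absorbance = absorbance, samples = samples),
    class = "spectra_set"
  )
}

#' @export
print.spectra_set <- function(x, ...) {
  counts <- table(factor(x$samples$split,
                         levels = c("calibration", "prediction", "external")),
                  useNA = "ifany")
  cat(sprintf("<spectra_set> %d samples x %d points (%.1f to %.1f cm^-1)\n",
              nrow(x$absorbance), x$grid$n_points,
              x$grid$values[1], x$grid$values[x$grid$n_points]))
  cat("  split: ", paste(names(counts), counts, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

is_spectra_set <- function(x) inherits(x, "spectra_set")

#' Long-format view of a spectra set
#'
#' @param x A `spectra_set`.
#' @param ... Unused.
#' @return A tibble with one row per (sample, wavenumber) pair, carrying the
#'   sample metadata alongside `wavenumber` and `absorbance`.
#' @method as_tibble spectra_set
#' @export
as_tibble.spectra_set <- function(x, ...) {
  wide <- as_tibble(x$absorbance, .name_repair = "minimal")
  names(wide) <- as.character(x$grid$values)
  dplyr::bind_cols(x$samples, wide) |>
    tidyr::pivot_longer(-dplyr::all_of(names(x$samples)),
                        names_to = "wavenumber", values_to = "absorbance") |>
    mutate(wavenumber = as.numeric(.data$wavenumber))
}

#' Subset a spectra set by sample
#'
#' @param set A `spectra_set`.
#' @param keep Logical or integer index over samples, or a split name.
#' @return A `spectra_set` containing the selected samples.
#' @export
subset_samples <- function(set, keep) {
  stopifnot(is_spectra_set(set))
  if (is.character(keep) && length(keep) == 1 &&
      keep %in% c("calibration", "prediction", "external")) {
    keep <- !is.na(set$samples$split) & set$samples$split == keep
  }
  spectra_set(set$absorbance[keep, , drop = FALSE],
              set$samples[keep, , drop = FALSE], set$grid)
}

#' Assign a stratified calibration/prediction split
#'
#' Within each quality grade, `round(ratio * n_grade)` samples are assigned
#' to the calibration set and the remainder to the prediction set, matching
#' the 3:1 grade-stratified design (42/14 for 8 samples in each of 7
#' grades at `ratio = 0.75`). Samples already flagged `external` keep their
#' flag and are never drawn into either set.
#'
#' @param set A `spectra_set` where every non-external sample has a grade.
#' @param ratio Calibration fraction, strictly between 0 and 1.
#' @param seed Integer seed making the within-grade draw reproducible.
#'
#' @return The `spectra_set` with its `split` column filled in.
#' @export
split_calibration <- function(set, ratio = 0.75, seed = 1L) {
  stopifnot(is_spectra_set(set))
  assert_number(ratio, "ratio")
  if (ratio <= 0 || ratio >= 1) abort("`ratio` must be in (0, 1).")
  samples <- set$samples
  pool <- which(is.na(samples$split) | samples$split != "external")
  if (any(is.na(samples$grade[pool]))) {
    abort("Every non-external sample must have a grade before splitting.")
  }
  split <- samples$split
  with_seed(seed, {
    for (g in sort(unique(samples$grade[pool]))) {
      idx <- pool[samples$grade[pool] == g]
      n_g <- length(idx)
      if (n_g < 2) {
        warn(sprintf(
          "Grade %s has %d sample(s); assigning all to calibration.", g, n_g))
        split[idx] <- "calibration"
        next
      }
      n_cal <- min(floor(ratio * n_g + 0.5), n_g) # half rounds up
      cal <- sample(idx, n_cal)
      split[cal] <- "calibration"
      split[setdiff(idx, cal)] <- "prediction"
    }
  })
  samples$split <- split
  spectra_set(set$absorbance, samples, set$grid)
}

# Absorbance + price for one split, the shape the modelling code consumes.
split_xy <- function(set, split = "calibration") {
  sub <- subset_samples(set, split)
  list(X = sub$absorbance, y = sub$samples$price, samples = sub$samples)
}
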