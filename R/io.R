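#' Read a spectra set from delimited text files
#'
#' The spectra file carries one header row (`sample_id` followed by the
#' descending wavenumbers) and one row of absorbances per sample. The
#' samples file carries `sample_id`, `grade`, `price_rmb_per_kg` and
#' `split` (which may be empty before splitting). Both are comma-delimited.
#'
#' @param spectra_path Path to the spectra table.
#' @param samples_path Path to the sample-metadata table.
#'
#' @return A [spectra_set()].
#' @export
read_spectra <- function(spectra_path, samples_path) {
  for (p in c(spectra_path, samples_path)) {
    if (!file.exists(p)) abort(sprintf("File not found: '%s'.", p))
  }
  spec <- readr::read_csv(spectra_path, show_col_types = FALSE,
                          progress = FALSE)
  if (names(spec)[1] != "sample_id") {
    abort("Spectra file must start with a 'sample_id' column.")
  }
  wn <- suppressWarnings(as.numeric(names(spec)[-1]))
  if (anyNA(wn)) {
    abort(sprintf("Non-numeric wavenumber header: '%s'.",
                  names(spec)[-1][which(is.na(wn))[1]]))
  }
  if (length(wn) < 2) abort("Spectra file needs at least two wavenumbers.")
  d <- diff(wn)
  if (any(d >= 0)) abort("Wavenumber header must be strictly descending.")
  step <- -mean(d)
  if (any(abs(d + step) > 1e-6 * step)) {
    abort("Wavenumber header is not evenly spaced.")
  }
  grid <- nir_grid(wn[1], step, length(wn))

  mat <- as.matrix(spec[-1])
  if (!is.numeric(mat)) {
    bad <- which(!vapply(spec[-1], is.numeric, logical(1)))[1]
    abort(sprintf("Non-numeric absorbance in column '%s'.",
                  names(spec[-1])[bad]))
  }

  samp <- readr::read_csv(samples_path, show_col_types = FALSE,
                          progress = FALSE,
                          col_types = readr::cols(
                            sample_id = readr::col_character(),
                            grade = readr::col_integer(),
                            price_rmb_per_kg = readr::col_double(),
                            split = readr::col_character()
                          ))
  needed <- c("sample_id", "grade", "price_rmb_per_kg", "split")
  miss <- setdiff(needed, names(samp))
  if (length(miss)) {
    abort(paste0("Samples file is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  samp <- samp |>
    dplyr::rename(price = "price_rmb_per_kg") |>
    dplyr::select(dplyr::all_of(c("sample_id", "grade", "price", "split")))
  if (!identical(as.character(spec$sample_id), samp$sample_id)) {
    # allow re-ordering as long as the id sets agree
    if (!setequal(spec$sample_id, samp$sample_id) ||
        nrow(spec) != nrow(samp)) {
      abort("Sample ids in the two files do not match.")
    }
    samp <- samp[match(spec$sample_id, samp$sample_id), ]
  }
  spectra_set(mat, samp, grid)
}

#' Write a spectra set to delimited text files
#'
#' Inverse of [read_spectra()]; absorbances are written with full double
#' precision so the round trip is numerically faithful.
#'
#' @param set A [spectra_set()].
#' @param spectra_path Output path for the spectra table.
#' @param samples_path Output path for the sample table.
#'
#' @return Invisibly, `set`.
#' @export
write_spectra <- function(set, spectra_path, samples_path) {
  stopifnot(is_spectra_set(set))
  for (p in c(spectra_path, samples_path)) {
    dir <- dirname(p)
    if (!dir.exists(dir)) abort(sprintf("Directory does not exist: '%s'.", dir))
  }
  wide <- as.data.frame(set$absorbance)
  names(wide) <- format(set$grid$values, digits = 15, trim = TRUE,
                        scientific = FALSE)
  wide <- dplyr::bind_cols(tibble(sample_id = set$samples$sample_id), wide)
  readr::write_csv(wide, spectra_path, progress = FALSE)
  set$samples |>
    dplyr::rename(price_rmb_per_kg = "price") |>
    readr::write_csv(samples_path, na = "", progress = FALSE)
  invisible(set)
}
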