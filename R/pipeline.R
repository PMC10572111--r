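#' Configuration for the full calibration pipeline
#'
#' One object drives the whole analysis: data acquisition (simulate or read
#' from files), the pretreatment comparison, si-PLS, the two GA tracks, PCA
#' compression and the network comparison. A single global `seed` fans out
#' to per-stage derived seeds, so any stage can be rerun in isolation.
#'
#' @param data One of: a [spectra_set()], a [sim_config()] (the dataset is
#'   generated, reseeded from `seed`), or a length-2 character vector
#'   `c(spectra_path, samples_path)`.
#' @param pretreat_window,pretreat_polyorder Savitzky-Golay parameters for
#'   the pretreatment catalogue.
#' @param sipls_interval_counts,sipls_combo_size si-PLS search space.
#' @param ga Named list of overrides for [ga_config()] (population size,
#'   generations, rates, ...).
#' @param ann Named list of overrides for [bpann_config()].
#' @param transfers Transfer functions to compare.
#' @param pca_components Principal components fed to the network.
#' @param max_factors PLS factor cap used throughout.
#' @param scheme CV scheme for the pretreatment comparison (`NULL` =
#'   leave-one-out for small calibration sets).
#' @param search_scheme CV scheme for the si-PLS and GA search stages
#'   (`NULL` = seeded 5-fold, the faster scheme for the enumeration).
#' @param ann_cv Whether the network comparison includes the leave-one-out
#'   RMSECV columns.
#' @param seed Global integer seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(data = sim_config(),
                            pretreat_window = 11, pretreat_polyorder = 2,
                            sipls_interval_counts = 10:25,
                            sipls_combo_size = 4,
                            ga = list(), ann = list(),
                            transfers = c("linear_sat", "tanh", "logistic"),
                            pca_components = 3, max_factors = 10,
                            scheme = NULL, search_scheme = NULL,
                            ann_cv = TRUE, seed = 1L) {
  ok_data <- is_spectra_set(data) || inherits(data, "sim_config") ||
    (is.character(data) && length(data) == 2)
  if (!ok_data) {
    abort(paste0("`data` must be a spectra_set, a sim_config, or ",
                 "c(spectra_path, samples_path)."))
  }
  structure(
    list(data = data, pretreat_window = pretreat_window,
         pretreat_polyorder = pretreat_polyorder,
         sipls_interval_counts = sipls_interval_counts,
         sipls_combo_size = sipls_combo_size,
         ga = ga, ann = ann, transfers = transfers,
         pca_components = assert_count(pca_components, "pca_components"),
         max_factors = assert_count(max_factors, "max_factors"),
         scheme = scheme, search_scheme = search_scheme,
         ann_cv = isTRUE(ann_cv), seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Pick the winning pretreatment from a comparison table
#'
#' Minimum RMSECV; ties break toward the recipe with fewer steps, then
#' catalogue order.
#'
#' @param table Tibble with columns `method`, `n_steps`, `rmsecv` (the
#'   `pretreat_table` of a pipeline report).
#' @return The winning row (one-row tibble).
#' @export
best_pretreatment <- function(table) {
  if (!is.data.frame(table) || nrow(table) == 0) {
    abort("Pretreatment table is empty.")
  }
  table |>
    arrange(.data$rmsecv, .data$n_steps, row_number()) |>
    dplyr::slice(1)
}

#' Run the full price-calibration pipeline
#'
#' Stages, in order: acquire data; compare the nine pretreatment recipes by
#' cross-validated PLS on the calibration set and keep the winner; si-PLS
#' interval search on the denoised spectra; GA point selection on the full
#' denoised spectrum (DSD track) and on the si-PLS-selected columns (FSD
#' track); PCA compression of each track's points; network comparison over
#' the transfer functions per track; external evaluation of the overall
#' best network.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `pipeline_report`; see the `print` method
#'   for the layout. All tables are tibbles.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  timings <- list()
  clock <- function(stage, expr) {
    t0 <- Sys.time()
    out <- force(expr)
    timings[[stage]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    out
  }

  set <- clock("data", {
    if (is_spectra_set(config$data)) {
      config$data
    } else if (inherits(config$data, "sim_config")) {
      cfg <- config$data
      cfg$seed <- derive_seed(seed, "simulate")
      generate_dataset(cfg)
    } else {
      read_spectra(config$data[1], config$data[2])
    }
  })
  cal <- split_xy(set, "calibration")
  if (length(cal$y) < 3) abort("Calibration set is too small.")
  scheme <- config$scheme %||% cv_default(length(cal$y))
  search_scheme <- config$search_scheme %||%
    cv_kfold(5, derive_seed(seed, "search-cv"))

  # -- pretreatment comparison ------------------------------------------
  catalogue <- pretreatment_catalogue(config$pretreat_window,
                                      config$pretreat_polyorder)
  pretreat_table <- clock("pretreat", purrr::map_dfr(catalogue, function(sp) {
    Xp <- apply_pretreatment(set, sp)$absorbance
    Xc <- Xp[set$samples$split == "calibration", , drop = FALSE]
    nf <- select_factors(Xc, cal$y, config$max_factors, scheme)
    preds <- cv_predictions(Xc, cal$y, nf, scheme)[, nf]
    tibble(method = pretreat_label(sp), n_steps = length(sp$steps),
           n_factors = as.integer(nf), rmsecv = rmse(cal$y, preds),
           r2cv = r_squared(cal$y, preds))
  }))
  best_pre <- best_pretreatment(pretreat_table)
  denoised <- apply_pretreatment(set, catalogue[[best_pre$method]])
  dcal <- split_xy(denoised, "calibration")
  dpred <- split_xy(denoised, "prediction")
  dext <- split_xy(denoised, "external")

  # -- si-PLS interval search -------------------------------------------
  sipls <- clock("sipls", sipls_search(
    dcal$X, dcal$y, denoised$grid,
    interval_counts = config$sipls_interval_counts,
    combo_size = config$sipls_combo_size,
    max_factors = config$max_factors, scheme = search_scheme))
  fsd_cols <- sipls_columns(sipls)

  # -- GA tracks ---------------------------------------------------------
  ga_run <- function(cands, tag) {
    args <- config$ga
    args$scheme <- args$scheme %||% search_scheme
    args$max_factors <- args$max_factors %||% config$max_factors
    args$seed <- derive_seed(seed, tag)
    ga_select(dcal$X, dcal$y, cands, do.call(ga_config, args),
              grid = denoised$grid)
  }
  ga_dsd <- clock("ga_dsd", ga_run(seq_len(ncol(dcal$X)), "ga-dsd"))
  ga_fsd <- clock("ga_fsd", ga_run(fsd_cols, "ga-fsd"))

  # -- PCA compression ---------------------------------------------------
  tracks <- list(dsd = ga_dsd, fsd = ga_fsd)
  pca <- clock("pca", lapply(tracks, function(g) {
    fit_pca(dcal$X[, g$selected_indices, drop = FALSE])
  }))
  k <- min(config$pca_components,
           min(map_dbl(pca, function(m) m$n_components)))
  scores <- lapply(names(tracks), function(nm) {
    cols <- tracks[[nm]]$selected_indices
    list(
      cal = pca_transform(pca[[nm]], dcal$X[, cols, drop = FALSE], k),
      pred = pca_transform(pca[[nm]], dpred$X[, cols, drop = FALSE], k),
      ext = if (length(dext$y)) {
        pca_transform(pca[[nm]], dext$X[, cols, drop = FALSE], k)
      }
    )
  })
  names(scores) <- names(tracks)

  # -- network comparison ------------------------------------------------
  ann_cfg <- do.call(bpann_config, c(config$ann,
                                     list(seed = derive_seed(seed, "ann"))))
  ann_tables <- clock("ann", lapply(names(tracks), function(nm) {
    compare_transfers(scores[[nm]]$cal, dcal$y,
                      scores[[nm]]$pred, dpred$y,
                      ann_cfg, config$transfers, cv = config$ann_cv)
  }))
  names(ann_tables) <- names(tracks)

  # -- external evaluation of the overall best network -------------------
  best_rows <- purrr::imap(ann_tables, function(tb, nm) {
    mutate(tb, track = nm)
  }) |> bind_rows() |> slice_min(.data$rmsep, n = 1, with_ties = FALSE)
  final_fit <- train_bpann(scores[[best_rows$track]]$cal, dcal$y,
                           best_rows$transfer, ann_cfg)
  external <- NULL
  if (length(dext$y)) {
    ep <- predict_price(final_fit, scores[[best_rows$track]]$ext)
    external <- list(
      table = tibble(sample_id = dext$samples$sample_id,
                     true = dext$y, predicted = ep),
      metrics = evaluate_predictions(dext$y, ep)
    )
  }

  structure(
    list(
      config = config,
      n_samples = nrow(set$absorbance),
      pretreat_table = pretreat_table,
      best_pretreatment = best_pre,
      sipls = sipls,
      ga = tracks,
      pca = pca,
      pca_components = as.integer(k),
      pca_table = purrr::imap(pca, function(m, nm) {
        tibble(track = nm,
               component = seq_len(min(6, m$n_components)),
               cumulative = cumulative_contributions(
                 m, min(6, m$n_components)))
      }) |> bind_rows(),
      ann_tables = ann_tables,
      best_model = list(track = best_rows$track,
                        transfer = best_rows$transfer,
                        rmsep = best_rows$rmsep, rp2 = best_rows$rp2,
                        fit = final_fit),
      external = external,
      timings = timings
    ),
    class = "pipeline_report"
  )
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  samples: %d | best pretreatment: %s (RMSECV %.3f)\n",
              x$n_samples, x$best_pretreatment$method,
              x$best_pretreatment$rmsecv))
  cat(sprintf("  si-PLS: %d intervals, combo [%s], RMSECV %.3f\n",
              x$sipls$best$n_intervals,
              paste(x$sipls$best$combo, collapse = " "),
              x$sipls$best$rmsecv))
  cat(sprintf("  GA: DSD %d points (RMSECV %.3f) | FSD %d points (RMSECV %.3f)\n",
              length(x$ga$dsd$selected_indices), x$ga$dsd$rmsecv,
              length(x$ga$fsd$selected_indices), x$ga$fsd$rmsecv))
  cat(sprintf("  best network: %s track, %s transfer, RMSEP %.3f (Rp2 %.3f)\n",
              x$best_model$track, x$best_model$transfer,
              x$best_model$rmsep, x$best_model$rp2))
  if (!is.null(x$external)) {
    cat(sprintf("  external: RMSEP %.3f, R2 %.3f (n = %d)\n",
                x$external$metrics$rmsep, x$external$metrics$r2,
                x$external$metrics$n))
  }
  invisible(x)
}

#' Evaluate a table of true and predicted prices
#'
#' Metadata-only evaluation: applies the package's error metrics to an
#' already-computed prediction table, e.g. the bundled external-validation
#' pairs.
#'
#' @param y_true,y_pred Numeric vectors of equal length.
#' @return A one-row tibble: `n`, `rmsep`, `r2`.
#' @export
evaluate_predictions <- function(y_true, y_pred) {
  tibble(n = length(y_true),
         rmsep = rmse(y_true, y_pred),
         r2 = r_squared(y_true, y_pred))
}

#' Bundled external-validation price pairs
#'
#' The 14 published true/predicted purchase-price pairs used to verify the
#' error metrics (see `inst/extdata/external_validation_pairs.csv`).
#'
#' @return A tibble with columns `no`, `true`, `predicted` (RMB/kg).
#' @export
external_validation_pairs <- function() {
  path <- system.file("extdata", "external_validation_pairs.csv",
                      package = "leafprice", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
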