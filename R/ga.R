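#' Genetic-algorithm configuration
#'
#' Hyperparameters for binary-chromosome wavenumber selection. Defaults are
#' common chemometrics-GA settings: population 64, 100 generations,
#' tournament size 3, one-point crossover at rate 0.8, per-bit mutation at
#' `1 / n_candidates`, elitism 2.
#'
#' @param population_size Chromosomes per generation (>= 2).
#' @param n_generations Generations to run.
#' @param crossover_rate Probability of one-point crossover per mating.
#' @param mutation_rate Per-bit flip probability; `NULL` means
#'   `1 / n_candidates`.
#' @param tournament_size Tournament size for selection.
#' @param elitism_count Best individuals copied unchanged
#'   (`< population_size`).
#' @param min_selected,max_selected Repair bounds on subset size
#'   (`max_selected = NULL` means no upper bound). No size penalty is
#'   applied: fitness is RMSECV alone.
#' @param max_factors PLS factor cap inside the fitness kernel.
#' @param scheme Cross-validation scheme for the fitness kernel (`NULL`
#'   means [cv_default()] for the sample count).
#' @param seed Integer seed; the run is fully reproducible given it.
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(population_size = 64, n_generations = 100,
                      crossover_rate = 0.8, mutation_rate = NULL,
                      tournament_size = 3, elitism_count = 2,
                      min_selected = 1, max_selected = NULL,
                      max_factors = 10, scheme = NULL, seed = 1L) {
  population_size <- assert_count(population_size, "population_size", 2L)
  elitism_count <- assert_count(elitism_count, "elitism_count", 0L)
  if (elitism_count >= population_size) {
    abort("`elitism_count` must be < `population_size`.")
  }
  for (r in c(crossover_rate, mutation_rate)) {
    if (!is.null(r) && (r < 0 || r > 1)) abort("Rates must be in [0, 1].")
  }
  structure(
    list(population_size = population_size,
         n_generations = assert_count(n_generations, "n_generations"),
         crossover_rate = crossover_rate, mutation_rate = mutation_rate,
         tournament_size = assert_count(tournament_size, "tournament_size"),
         elitism_count = elitism_count,
         min_selected = assert_count(min_selected, "min_selected"),
         max_selected = max_selected,
         max_factors = assert_count(max_factors, "max_factors"),
         scheme = scheme, seed = as.integer(seed)),
    class = "ga_config"
  )
}

#' Genetic-algorithm selection of wavenumber points
#'
#' Binary-chromosome GA over a candidate column set (full spectrum or an
#' si-PLS-selected subset): each bit marks one candidate column, fitness is
#' the negated cross-validated PLS RMSECV on the active columns (factor
#' count chosen by [select_factors()]). Tournament selection, one-point
#' crossover, per-bit mutation and elitism; empty chromosomes are repaired
#' by activating one random bit. The population is initialized sparsely
#' (expected ~20 active bits for large candidate pools, the regime where
#' selection-curve minima live), with the all-ones chromosome plus ten very
#' sparse chromosomes injected, so the best-ever RMSECV can never exceed
#' that of the full candidate set.
#'
#' @param X Calibration absorbance matrix.
#' @param y Calibration prices (RMB/kg).
#' @param candidate_indices Columns of `X` the GA may pick
#'   (default: all).
#' @param config A [ga_config()].
#' @param grid Optional [nir_grid()] to report selected wavenumbers.
#' @return An object of class `ga_result`: `selected_indices` (columns of
#'   `X`, sorted), `selected_wavenumbers`, `rmsecv`, `n_factors`, `history`
#'   (per-generation best-ever trace) and `curve` (best RMSECV per subset
#'   size over all evaluations).
#' @export
ga_select <- function(X, y, candidate_indices = seq_len(ncol(X)),
                      config = ga_config(), grid = NULL) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (length(candidate_indices) == 0) abort("Candidate set is empty.")
  if (any(candidate_indices < 1 | candidate_indices > ncol(X))) {
    abort("`candidate_indices` out of range.")
  }
  if (var(y) == 0) abort("`y` has zero variance.")
  candidate_indices <- sort(unique(as.integer(candidate_indices)))
  nc <- length(candidate_indices)
  Xc <- X[, candidate_indices, drop = FALSE]
  scheme <- config$scheme %||% cv_default(nrow(Xc))
  folds <- cv_folds(scheme, nrow(Xc))
  mut <- config$mutation_rate %||% (1 / nc)

  memo <- new.env(parent = emptyenv())
  size_best <- new.env(parent = emptyenv())
  eval_bits <- function(bits) {
    key <- paste(which(bits), collapse = ",")
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    cols <- which(bits)
    trace <- cv_trace_lean(Xc[, cols, drop = FALSE], y,
                           min(config$max_factors, length(cols),
                               nrow(Xc) - 1L),
                           folds)
    nf <- which.min(trace)
    out <- list(rmsecv = trace[nf], n_factors = as.integer(nf))
    memo[[key]] <- out
    sk <- as.character(length(cols))
    if (is.null(size_best[[sk]]) || out$rmsecv < size_best[[sk]]) {
      size_best[[sk]] <- out$rmsecv
    }
    out
  }
  repair <- function(bits) {
    k <- sum(bits)
    if (k < config$min_selected) {
      off <- which(!bits)
      bits[off[sample.int(length(off),
                          min(config$min_selected - k, length(off)))]] <- TRUE
    }
    if (!is.null(config$max_selected) && sum(bits) > config$max_selected) {
      on <- which(bits)
      bits[sample(on, sum(bits) - config$max_selected)] <- FALSE
    }
    bits
  }

  with_seed(config$seed, {
    np <- config$population_size
    # sparse initialization (expected ~20 active bits for large candidate
    # pools) so the population explores the small-subset regime where the
    # selection-curve minimum lives
    p0 <- min(0.5, 20 / nc)
    pop <- matrix(runif(np * nc) < p0, np, nc)
    pop[1, ] <- TRUE # full candidate set, guaranteeing the full-set bound
    n_sparse <- min(10L, np - 1L)
    for (i in seq_len(n_sparse)) {
      row <- rep(FALSE, nc)
      row[sample.int(nc, max(config$min_selected,
                             min(nc, sample(2:5, 1))))] <- TRUE
      pop[1L + i, ] <- row
    }
    pop <- t(apply(pop, 1, repair))
    if (nc == 1) pop <- matrix(pop, ncol = 1)

    best <- NULL
    history <- vector("list", config$n_generations)
    for (gen in seq_len(config$n_generations)) {
      evals <- apply(pop, 1, eval_bits)
      fits <- -map_dbl(evals, "rmsecv")
      gi <- which.max(fits)
      if (is.null(best) || -fits[gi] < best$rmsecv) {
        best <- list(bits = pop[gi, ], rmsecv = -fits[gi],
                     n_factors = evals[[gi]]$n_factors)
      }
      history[[gen]] <- tibble(
        generation = gen,
        best_rmsecv = best$rmsecv,
        generation_rmsecv = -fits[gi],
        best_size = sum(best$bits)
      )
      if (gen == config$n_generations) break

      elite_idx <- order(fits, decreasing = TRUE)[
        seq_len(config$elitism_count)]
      new_pop <- matrix(FALSE, np, nc)
      if (config$elitism_count > 0) {
        new_pop[seq_along(elite_idx), ] <- pop[elite_idx, , drop = FALSE]
      }
      pick <- function() {
        contenders <- sample.int(np, min(config$tournament_size, np))
        contenders[which.max(fits[contenders])]
      }
      slot <- config$elitism_count
      while (slot < np) {
        p1 <- pop[pick(), ]
        p2 <- pop[pick(), ]
        if (runif(1) < config$crossover_rate && nc > 1) {
          cut <- sample.int(nc - 1L, 1L)
          c1 <- c(p1[1:cut], p2[(cut + 1):nc])
          c2 <- c(p2[1:cut], p1[(cut + 1):nc])
        } else {
          c1 <- p1; c2 <- p2
        }
        for (child in list(c1, c2)) {
          if (slot >= np) break
          flip <- runif(nc) < mut
          child <- xor(child, flip)
          if (!any(child)) child[sample.int(nc, 1)] <- TRUE
          slot <- slot + 1L
          new_pop[slot, ] <- repair(child)
        }
      }
      pop <- new_pop
    }
  })

  sel <- candidate_indices[which(best$bits)]
  curve <- tibble(
    size = as.integer(ls(size_best)),
    rmsecv = map_dbl(ls(size_best), function(k) size_best[[k]])
  ) |> arrange(.data$size)

  structure(
    list(
      selected_indices = sel,
      selected_wavenumbers = if (!is.null(grid)) grid$values[sel] else NULL,
      rmsecv = best$rmsecv,
      n_factors = best$n_factors,
      n_candidates = nc,
      history = bind_rows(history),
      curve = curve,
      config = config
    ),
    class = "ga_result"
  )
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf(
    "<ga_result> %d of %d candidate points selected, RMSECV %.3f (%d factors)\n",
    length(x$selected_indices), x$n_candidates, x$rmsecv, x$n_factors))
  invisible(x)
}

#' Selected wavenumber points as a tibble
#' @param x A `ga_result`.
#' @param ... Unused.
#' @return A tibble with `index` (column in the original matrix) and, when
#'   a grid was supplied, `wavenumber`.
#' @method tidy ga_result
#' @export
tidy.ga_result <- function(x, ...) {
  out <- tibble(index = x$selected_indices)
  if (!is.null(x$selected_wavenumbers)) {
    out$wavenumber <- x$selected_wavenumbers
  }
  out
}

#' One-row summary of a GA selection run
#' @param x A `ga_result`.
#' @param ... Unused.
#' @return A one-row tibble: `n_selected`, `n_candidates`, `rmsecv`,
#'   `n_factors`, `n_generations`.
#' @method glance ga_result
#' @export
glance.ga_result <- function(x, ...) {
  tibble(
    n_selected = length(x$selected_indices),
    n_candidates = x$n_candidates,
    rmsecv = x$rmsecv,
    n_factors = x$n_factors,
    n_generations = max(x$history$generation)
  )
}

#' Best RMSECV per subset size seen during a GA run
#'
#' The classic selection curve: as more points are allowed in, RMSECV
#' drops to a minimum and then creeps back up.
#'
#' @param result A `ga_result`.
#' @return A tibble with `size` and `rmsecv` (minimum ever observed at
#'   that subset size).
#' @export
selection_curve <- function(result) {
  stopifnot(inherits(result, "ga_result"))
  result$curve
}

#' Plot the GA selection curve
#' @param object A `ga_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ga_result
#' @export
autoplot.ga_result <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$size, y = .data$rmsecv)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = length(object$selected_indices),
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "Number of selected spectral points",
                  y = "Best RMSECV (RMB/kg)",
                  title = "GA selection curve") +
    ggplot2::theme_minimal()
}
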