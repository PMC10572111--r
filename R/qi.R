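#' Quality index of fresh leaves
#'
#' `QI = humidity * total_nitrogen / crude_fiber`, all three as mass
#' fractions; higher QI means better raw-leaf quality.
#'
#' @param humidity,total_nitrogen,crude_fiber Numeric vectors (recycled);
#'   `crude_fiber` must be positive.
#' @return Numeric QI vector.
#' @export
quality_index <- function(humidity, total_nitrogen, crude_fiber) {
  if (any(crude_fiber <= 0)) abort("`crude_fiber` must be positive.")
  humidity * total_nitrogen / crude_fiber
}

#' Paired t-test between two grade's QI values
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` for the paired differences
#' `d = a - b`, with `n - 1` degrees of freedom, flagged against the
#' two-sided 0.05 and 0.01 critical values.
#'
#' @param qi_a,qi_b Numeric vectors of equal length (`>= 2`).
#' @return A one-row tibble: `t_statistic`, `df`, `p_value`,
#'   `significant_05`, `significant_01`.
#' @export
paired_t <- function(qi_a, qi_b) {
  if (length(qi_a) != length(qi_b)) {
    abort("`qi_a` and `qi_b` must have the same length.")
  }
  if (length(qi_a) < 2) abort("Need at least two pairs.")
  d <- qi_a - qi_b
  if (sd(d) == 0) {
    abort("Paired differences have zero variance; t is undefined.")
  }
  ht <- t.test(qi_a, qi_b, paired = TRUE)
  df <- length(d) - 1L
  tibble(
    t_statistic = unname(ht$statistic),
    df = df,
    p_value = ht$p.value,
    significant_05 = abs(ht$statistic) > t_critical(0.05, df),
    significant_01 = abs(ht$statistic) > t_critical(0.01, df)
  )
}

#' Two-sided critical value of Student's t
#'
#' @param alpha Significance level in (0, 1).
#' @param df Degrees of freedom (`>= 1`).
#' @param two_sided Use the two-sided quantile (default).
#' @return The critical t value (e.g. 2.365 at `alpha = 0.05`, `df = 7`).
#' @export
t_critical <- function(alpha, df, two_sided = TRUE) {
  assert_number(alpha, "alpha")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  df <- assert_count(df, "df")
  qt(1 - if (two_sided) alpha / 2 else alpha, df)
}

#' All pairwise QI t-tests between grades
#'
#' The upper triangle of the grade-by-grade paired t matrix.
#'
#' @param data Data frame with columns `grade` and `qi` (e.g. the sample
#'   table of a simulated [spectra_set()]).
#' @return A tibble with one row per grade pair: `grade_a`, `grade_b` and
#'   the [paired_t()] columns. Grades must have equal sample counts.
#' @export
qi_pairwise_tests <- function(data) {
  if (!all(c("grade", "qi") %in% names(data))) {
    abort("`data` needs columns `grade` and `qi`.")
  }
  data <- data[!is.na(data$grade), ]
  grades <- sort(unique(data$grade))
  if (length(grades) < 2) abort("Need at least two grades.")
  counts <- table(data$grade)
  if (length(unique(counts)) != 1) {
    abort("All grades must have the same number of samples for pairing.")
  }
  pairs <- combn(grades, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    res <- paired_t(data$qi[data$grade == a], data$qi[data$grade == b])
    dplyr::bind_cols(tibble(grade_a = a, grade_b = b), res)
  })
}

#' Ordinary least-squares fit report
#'
#' Simple linear regression of `y` on `x` with R^2 computed from the
#' fitted values, for the pairwise grade/QI/price relationships.
#'
#' @param x,y Numeric vectors, `n >= 3`, `x` not constant.
#' @return A one-row tibble: `slope`, `intercept`, `r_squared`.
#' @export
linear_fit_report <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 3) abort("Need at least three points.")
  if (var(x) == 0) abort("`x` is constant; the fit is undefined.")
  fit <- lm(y ~ x)
  tibble(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = r_squared(y, unname(fitted(fit)))
  )
}

#' Percent decrease of the quality index
#'
#' `100 * (qi_high - qi_low) / qi_high`, the drop from the best grade's QI
#' to the worst grade's, in percent.
#'
#' @param qi_high Reference (higher) QI, positive.
#' @param qi_low Comparison QI.
#' @return Percent decrease.
#' @export
qi_percent_change <- function(qi_high, qi_low) {
  assert_number(qi_high, "qi_high")
  assert_number(qi_low, "qi_low")
  if (qi_high <= 0) abort("`qi_high` must be positive.")
  100 * (qi_high - qi_low) / qi_high
}
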