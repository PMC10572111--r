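#' Root mean square error
#'
#' `sqrt(sum((y_true - y_pred)^2) / n)`. Called RMSECV when the predictions
#' are cross-validated and RMSEP when they come from an independent
#' prediction set; units follow the response (RMB/kg for prices).
#'
#' @param y_true,y_pred Numeric vectors of equal length.
#' @return A single non-negative number.
#' @export
rmse <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    abort("`y_true` and `y_pred` must have the same length.")
  }
  if (length(y_true) < 1) abort("Need at least one observation.")
  sqrt(mean((y_true - y_pred)^2))
}

#' Coefficient of determination
#'
#' `1 - sum((y_pred - y_true)^2) / sum((y_true - mean(y_true))^2)`.
#'
#' @param y_true,y_pred Numeric vectors of equal length, `n >= 2`.
#' @return A single number `<= 1` (negative when predictions are worse than
#'   the mean).
#' @export
r_squared <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    abort("`y_true` and `y_pred` must have the same length.")
  }
  if (length(y_true) < 2) abort("Need at least two observations.")
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) abort("`y_true` is constant; R^2 is undefined.")
  1 - sum((y_pred - y_true)^2) / ss_tot
}

#' Percent change between two values
#'
#' `100 * (to - from) / from`: positive when the quantity increased.
#'
#' @param from Baseline value (non-zero).
#' @param to New value.
#' @return Percent change.
#' @export
percent_change <- function(from, to) {
  assert_number(from, "from")
  assert_number(to, "to")
  if (from == 0) abort("`from` must be non-zero.")
  100 * (to - from) / from
}
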