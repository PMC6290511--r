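# Regression metrics for the continuous primary target.

check_pair <- function(y, y_hat) {
  if (length(y) != length(y_hat)) {
    stop("y and y_hat must have equal length", call. = FALSE)
  }
  if (length(y) < 1L) stop("need at least one observation", call. = FALSE)
  invisible(TRUE)
}

#' Mean squared error
#'
#' @param y,y_hat Numeric vectors of equal length.
#' @return `mean((y - y_hat)^2)`.
#' @export
mse <- function(y, y_hat) {
  check_pair(y, y_hat)
  mean((y - y_hat)^2)
}

#' Explained variance score
#'
#' `1 - Var(y - y_hat) / Var(y)`. Shift-invariant: a prediction off by a
#' constant still scores 1. The variance convention (population vs sample)
#' cancels in the ratio. Larger is better; 1 is perfect.
#'
#' @param y,y_hat Numeric vectors of equal length; `Var(y)` must be positive.
#' @return Real number `<= 1`.
#' @export
evs <- function(y, y_hat) {
  check_pair(y, y_hat)
  v <- stats::var(y)
  if (!is.finite(v) || v == 0) {
    stop("evs: Var(y) must be positive", call. = FALSE)
  }
  1 - stats::var(y - y_hat) / v
}

#' Median absolute error
#'
#' The MEDIAN of the absolute residuals (not the mean) — robust to a few
#' large errors. For an even number of residuals the midpoint of the two
#' central order statistics is used.
#'
#' @param y,y_hat Numeric vectors of equal length.
#' @return Nonnegative scalar.
#' @export
mae <- function(y, y_hat) {
  check_pair(y, y_hat)
  stats::median(abs(y - y_hat))
}

#' All three regression metrics as a one-row tibble
#'
#' @param y,y_hat Numeric vectors of equal length.
#' @return Tibble with columns `mse`, `evs`, `mae`, `n`.
#' @export
metric_report <- function(y, y_hat) {
  tibble::tibble(mse = mse(y, y_hat), evs = evs(y, y_hat),
                 mae = mae(y, y_hat), n = length(y))
}
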