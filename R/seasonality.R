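#' Centered moving average of a monthly series
#'
#' Classical even-window smoother for monthly data: the 12-term moving
#' average computed at the two placements straddling each month, averaged —
#' equivalently a 13-term weighted mean with weights 1/24, 1/12 (x11), 1/24.
#' The result is aligned to the series center: the first smoothed value
#' corresponds to input position `window/2 + 1` (position 7 for monthly
#' data), and the output has length `n - window`. The CMA removes any exact
#' 12-month periodic component and reproduces affine trends exactly.
#'
#' @param series numeric vector, length > `window`.
#' @param window even smoothing span, default 12 (months).
#' @return numeric vector of length `length(series) - window`, with attribute
#'   `offset` = `window/2` (number of leading input positions without a
#'   smoothed value).
#' @export
centered_moving_average <- function(series, window = 12L) {
  window <- as.integer(window)
  if (window < 2L || window %% 2L != 0L) stop("window must be a positive even integer")
  n <- length(series)
  if (n <= window) stop("series must be longer than the smoothing window (need > ",
                        window, " points, got ", n, ")")
  if (any(!is.finite(series))) stop("series must be finite")
  h <- window %/% 2L
  cs <- cumsum(c(0, series))
  i <- (h + 1L):(n - h)                       # centered positions
  ma_left <- cs[i + h] - cs[i - h]            # window ending at i + h - 1
  ma_right <- cs[i + h + 1L] - cs[i - h + 1L] # window ending at i + h
  out <- (ma_left + ma_right) / (2 * window)
  attr(out, "offset") <- h
  out
}

#' Multiplicative seasonal decomposition with linear trend
#'
#' Ratio-to-moving-average decomposition of a strictly positive monthly rate
#' series: a 12-month centered moving average estimates the trend-cycle;
#' per-month ratios series/CMA are averaged by calendar month and
#' renormalized to mean 1 to give the 12 seasonal indices; the series divided
#' by its month's index is the deseasonalized series, whose ordinary
#' least-squares regression on the 1-based month index t gives the linear
#' trend. The leading and trailing `window/2` months have no CMA value and
#' are excluded from index estimation (not padded).
#'
#' @param series strictly positive monthly values, length >= 24.
#' @param start_month calendar month (1-12) of the first observation;
#'   default 1. Panels anchored elsewhere (e.g. a July fiscal-year start)
#'   must pass their own anchor so indices land on the right calendar month.
#' @return list with class `seasonal_fit`: `seasonal_index` (named numeric,
#'   Jan..Dec, mean 1), `trend_slope`, `trend_intercept` (units of the input
#'   series per month, intercept at t = 0), `smoothed` (the CMA, length
#'   n - 12), `deseasonalized` (length n).
#' @export
seasonal_decompose <- function(series, start_month = 1L) {
  n <- length(series)
  if (n < 24L) stop("need at least 24 months to estimate seasonal indices")
  if (any(!is.finite(series)) || any(series <= 0))
    stop("multiplicative decomposition requires strictly positive values")
  start_month <- as.integer(start_month)
  if (start_month < 1L || start_month > 12L) stop("start_month must be in 1..12")

  cma <- centered_moving_average(series, 12L)
  h <- attr(cma, "offset")
  months <- ((start_month - 1L + seq_len(n) - 1L) %% 12L) + 1L

  mid <- (h + 1L):(n - h)
  ratio <- series[mid] / cma
  idx <- vapply(1:12, function(m) mean(ratio[months[mid] == m]), numeric(1))
  if (anyNA(idx)) stop("some calendar month has no interior observation")
  idx <- idx / mean(idx)
  names(idx) <- month.abb

  deseason <- series / idx[months]
  t <- seq_len(n)
  fit <- stats::lm.fit(cbind(1, t), deseason)
  structure(list(seasonal_index = idx,
                 trend_slope = unname(fit$coefficients[2L]),
                 trend_intercept = unname(fit$coefficients[1L]),
                 smoothed = as.numeric(cma),
                 deseasonalized = unname(deseason)),
            class = "seasonal_fit")
}

#' @export
print.seasonal_fit <- function(x, ...) {
  cat("Multiplicative seasonal fit\n")
  cat("  trend: y =", format(x$trend_slope, digits = 3), "* t +",
      format(x$trend_intercept, digits = 3), " (t = month, 1-based)\n")
  cat("  seasonal indices (mean 1):\n")
  print(round(x$seasonal_index, 3))
  invisible(x)
}
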