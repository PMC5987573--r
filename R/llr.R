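#' Poisson window log-likelihood ratio
#'
#' The discrete-Poisson scan-statistic likelihood ratio for a candidate
#' window, in log space. With C total cases, c observed in the window and
#' E(c) expected in the window under proportional risk, the window
#' likelihood is proportional to (c/E)^c ((C-c)/(C-E))^(C-c) I(), so
#'
#'   LLR = c log(c/E) + (C - c) log((C-c)/(C-E))
#'
#' when the window has an excess (c > E, the high-rate indicator I() = 1),
#' and 0 otherwise. The c = 0 and c = C log terms are taken as 0 by the
#' usual 0 log 0 = 0 convention. For fixed E and C the statistic is strictly
#' increasing in c on c > E.
#'
#' @param c observed cases in the window, 0 <= c <= total_cases. Vectorized.
#' @param expected expected cases E(c) in the window, 0 < E < total_cases.
#' @param total_cases panel total C.
#' @param high_rates_only if TRUE (default) the one-sided high-rate indicator
#'   is applied and windows with c <= E score 0; if FALSE the two-sided LLR
#'   is returned (positive for deficits too).
#' @return non-negative LLR value(s).
#' @export
poisson_llr <- function(c, expected, total_cases, high_rates_only = TRUE) {
  if (any(expected <= 0)) stop("expected must be positive")
  if (any(expected >= total_cases)) stop("expected must be below total_cases")
  if (any(c < 0) || any(c > total_cases)) stop("c must lie in [0, total_cases]")
  C <- total_cases
  t_in <- ifelse(c > 0, c * log(c / expected), 0)
  t_out <- ifelse(C - c > 0, (C - c) * log((C - c) / (C - expected)), 0)
  llr <- t_in + t_out
  if (high_rates_only) llr <- ifelse(c > expected, llr, 0)
  llr
}

#' Window relative risk
#'
#' Rate inside the window relative to the rate outside it:
#' RR = (c/E) / ((C-c)/(C-E)). Equals 1 when c = E; undefined for a window
#' holding every case.
#'
#' @inheritParams poisson_llr
#' @return relative risk value(s).
#' @export
window_relative_risk <- function(c, expected, total_cases) {
  if (any(expected <= 0)) stop("expected must be positive")
  if (any(expected >= total_cases)) stop("expected must be below total_cases")
  if (any(c >= total_cases))
    stop("relative risk undefined for a window containing all cases")
  C <- total_cases
  (c / expected) / ((C - c) / (C - expected))
}
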