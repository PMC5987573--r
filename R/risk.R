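#' Expected counts under spatial-temporal randomness
#'
#' The null model of proportional risk: each cell's expectation is its share
#' of total person-time, E(unit, m) = p(unit, m) * C / P, where C is the
#' panel total of cases and P the panel total of person-time. By construction
#' the expected counts sum exactly to C, and they are invariant to rescaling
#' all person-time by a constant.
#'
#' @param cases a [case_panel()].
#' @param pop a [population_panel()] on the same (unit, month) index.
#' @return numeric matrix of expectations, same dimnames as the panels.
#' @export
expected_counts <- function(cases, pop) {
  check_same_index(cases, pop)
  C <- sum(cases)
  P <- sum(pop)
  E <- unclass(pop) * (C / P)
  attributes(E) <- attributes(unclass(pop))[c("dim", "dimnames")]
  E
}

#' Per-unit excess risk (SMR) and relative risk table
#'
#' Aggregates a panel to one row per unit: observed cases c, expected cases E
#' under proportional person-time, the excess risk (observed over expected;
#' the standardized morbidity ratio), and the relative risk against the
#' outside-unit baseline, RR = (c/E) / ((C-c)/(C-E)). Rows are sorted by
#' excess risk, descending.
#'
#' @param cases a [case_panel()].
#' @param pop a [population_panel()] on the same index.
#' @return data.frame: unit_id, observed, expected, obs_over_exp,
#'   relative_risk.
#' @export
excess_risk_table <- function(cases, pop) {
  E <- expected_counts(cases, pop)
  C <- sum(cases)
  obs <- rowSums(cases)
  exp_u <- rowSums(E)
  if (any(abs(exp_u - C) < 1e-9 * C))
    stop("relative risk undefined: a single unit holds all expected cases")
  out <- data.frame(
    unit_id = rownames(cases),
    observed = unname(obs),
    expected = unname(exp_u),
    obs_over_exp = unname(obs / exp_u),
    relative_risk = unname((obs / exp_u) / ((C - obs) / (C - exp_u)))
  )
  out <- out[order(-out$obs_over_exp, out$unit_id), ]
  rownames(out) <- NULL
  out
}
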