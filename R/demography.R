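#' Population projection configuration
#'
#' Parameters for compound-growth projection of the population at risk,
#' P(t) = Po (1 + r)^t with t in years from the reference year. The
#' under-five sub-population is taken as a fixed fraction of the total.
#'
#' @param annual_growth_rate proportion per year (r); default 0.029, the
#'   regional growth rate used for the Sidama panel.
#' @param underfive_fraction proportion of total population under five years
#'   of age; default 0.156 (SNNPR).
#' @param reference_population optional reference (base-year) population Po.
#'   May be omitted when projecting from a location table, which carries its
#'   own base populations.
#' @param reference_year calendar year of Po.
#' @return list with class `projection_config`.
#' @export
projection_config <- function(annual_growth_rate = 0.029,
                              underfive_fraction = 0.156,
                              reference_population = NULL,
                              reference_year = 2011L) {
  if (annual_growth_rate <= -1) stop("annual_growth_rate must exceed -1")
  if (underfive_fraction <= 0 || underfive_fraction >= 1)
    stop("underfive_fraction must be in (0, 1)")
  if (!is.null(reference_population) && reference_population <= 0)
    stop("reference_population must be positive")
  structure(list(annual_growth_rate = annual_growth_rate,
                 underfive_fraction = underfive_fraction,
                 reference_population = reference_population,
                 reference_year = as.integer(reference_year)),
            class = "projection_config")
}

#' Project a population forward by compound growth
#'
#' P = Po (1 + r)^t. With `underfive = TRUE` the result is additionally
#' scaled by the configured under-five fraction.
#'
#' @param config a [projection_config()] with `reference_population` set, or
#'   a bare positive number taken as Po (then `rate` must be given).
#' @param elapsed_years non-negative time from the reference year; fractional
#'   years give smooth monthly interpolation.
#' @param underfive scale by the under-five fraction? Default FALSE.
#' @param rate growth rate override when `config` is a bare Po.
#' @return projected persons (vectorized over `elapsed_years`).
#' @export
project_population <- function(config, elapsed_years, underfive = FALSE,
                               rate = NULL) {
  if (inherits(config, "projection_config")) {
    po <- config$reference_population
    if (is.null(po)) stop("projection_config has no reference_population")
    r <- config$annual_growth_rate
    f <- config$underfive_fraction
  } else {
    po <- config
    if (is.null(rate)) stop("rate must be supplied with a bare population")
    r <- rate
    f <- NA_real_
  }
  if (any(elapsed_years < 0)) stop("elapsed_years must be non-negative")
  p <- po * (1 + r)^elapsed_years
  if (underfive) {
    if (is.na(f)) stop("no underfive_fraction available")
    p <- p * f
  }
  p
}

#' Monthly person-time panel from base populations
#'
#' Expands a location table's base populations into a (unit x month) panel of
#' person-months, compounding the annual growth rate continuously:
#' person_time(unit, m) = base_population(unit) * (1 + r)^(m / 12) for
#' 0-based month index m. At m = 12 each unit equals exactly one annual
#' compounding step.
#'
#' @param locations a [location_table()]; `base_population` is interpreted as
#'   the population at risk at month 0 (already the under-five population —
#'   apply [project_population()]'s `underfive` scaling upstream if starting
#'   from total census counts).
#' @param config a [projection_config()] supplying the growth rate.
#' @param n_months panel length, >= 1.
#' @param start_month,start_year calendar anchoring of month 0.
#' @return A [population_panel()].
#' @export
monthly_population_panel <- function(locations, config, n_months,
                                     start_month = 7L, start_year = 2011L) {
  locations <- location_table(as.data.frame(locations))
  if (!inherits(config, "projection_config")) stop("config must be a projection_config")
  n_months <- as.integer(n_months)
  if (n_months < 1L) stop("n_months must be >= 1")
  growth <- (1 + config$annual_growth_rate)^((seq_len(n_months) - 1L) / 12)
  pt <- outer(locations$base_population, growth)
  rownames(pt) <- locations$unit_id
  population_panel(pt, start_month = start_month, start_year = start_year)
}

#' Incidence rate
#'
#' cases / person_time * per. The conventional reporting scales are per 1000
#' (district yearly rates) and per 100,000 (zonal annual rate).
#'
#' @param cases case count(s).
#' @param person_time population at risk over the same period; must be > 0.
#' @param per reporting scale, default 1000.
#' @return rate(s) on the `per` scale.
#' @export
incidence_rate <- function(cases, person_time, per = 1000) {
  if (any(person_time <= 0)) stop("person_time must be positive")
  cases / person_time * per
}

#' Yearly incidence rates per unit
#'
#' Aggregates a monthly panel into fiscal-year incidence rates per unit:
#' yearly cases divided by the mean monthly population of that year, on the
#' `per` scale. Years are consecutive 12-month blocks from panel start;
#' a trailing partial year is dropped.
#'
#' @param cases a [case_panel()].
#' @param pop a [population_panel()] on the same index.
#' @param per reporting scale, default 1000.
#' @return data.frame: unit_id, one column per 12-month block.
#' @export
yearly_rate_table <- function(cases, pop, per = 1000) {
  check_same_index(cases, pop)
  ny <- ncol(cases) %/% 12L
  if (ny < 1L) stop("panel shorter than 12 months")
  out <- data.frame(unit_id = rownames(cases))
  for (y in seq_len(ny)) {
    cols <- ((y - 1L) * 12L + 1L):(y * 12L)
    out[[paste0("year", y)]] <-
      incidence_rate(rowSums(cases[, cols, drop = FALSE]),
                     rowMeans(pop[, cols, drop = FALSE]), per = per)
  }
  out
}
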