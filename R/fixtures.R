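#' Published reference tables for the Sidama Zone diarrhea panel
#'
#' In-memory copies of the printed result tables from a published
#' district-level analysis of under-five diarrhea morbidity in Sidama Zone,
#' Southern Ethiopia (HMIS monthly reports, July 2011 to June 2017, 19 rural
#' districts). The raw monthly panel behind them was never deposited, so these
#' printed aggregates are the only quantitative anchor available: they are
#' used as benchmark fixtures for the likelihood, relative-risk and
#' excess-risk computations, and to shape the synthetic scenario in
#' [reference_scenario()].
#'
#' Values are transcribed exactly as printed; internal consistency (for
#' example that observed/expected ratios follow from the printed observed and
#' expected columns) is asserted by the test suite, not silently corrected.
#' Month indices in `table4` and `temporal_cluster` are 0-based from July
#' 2011 (month 0) through June 2017 (month 71).
#'
#' @return A list with components:
#' \describe{
#'   \item{table1}{yearly incidence rates per 1000 under-five children, 19
#'     districts x 6 fiscal years (July-June), plus the printed per-year
#'     averages in `attr(, "printed_average")`.}
#'   \item{table2}{district-level excess risk: observed, expected,
#'     observed/expected (SMR) and relative risk for all 19 districts.}
#'   \item{table3}{the purely spatial clusters: one primary (rank 1) and six
#'     secondary, with population, coordinates, observed, expected, annual
#'     cases per 100,000, observed/expected, RR and LLR.}
#'   \item{table4}{the space-time clusters (cylinders), with time frames both
#'     as printed dates and as 0-based month indices.}
#'   \item{temporal_cluster}{the single purely temporal cluster
#'     (December 2013 to May 2015, all districts).}
#'   \item{total_cases}{202406, the panel total C.}
#'   \item{annual_rate_per_100k}{5822, reported annual incidence per 100,000.}
#'   \item{growth_rate}{0.029, regional annual population growth rate.}
#'   \item{underfive_fraction}{0.156, under-five share of total population.}
#'   \item{trend}{reported deseasonalized linear trend, slope 0.015 per month
#'     and intercept 4.27 (rate per 1000 scale); not re-derivable without the
#'     unpublished monthly series.}
#' }
#' @export
sidama_tables <- function() {
  years <- c("2011/12", "2012/13", "2013/14", "2014/15", "2015/16", "2016/17")

  t1 <- rbind(
    "Aleta Chuko"   = c(56.0, 44.9, 57.9, 56.6, 61.2, 54.7),
    "Aleta Wondo"   = c(56.0, 64.0, 84.7, 95.4, 60.2, 70.6),
    "Arbegona"      = c(52.4, 42.5, 63.9, 68.3, 43.9, 52.0),
    "Aroresa"       = c(31.6, 35.5, 43.8, 27.7, 22.4, 31.2),
    "Bensa"         = c(24.5, 18.3, 26.1, 27.9, 17.5, 17.3),
    "Bona"          = c(26.1, 49.1, 51.2, 48.1, 40.2, 65.2),
    "Boricha"       = c(88.3, 62.0, 85.1, 121.8, 95.7, 135.8),
    "Bursa"         = c(50.7, 31.4, 33.9, 26.7, 24.2, 17.5),
    "Chirie"        = c(18.6, 91.3, 82.7, 37.4, 17.3, 27.2),
    "Dale"          = c(115.2, 38.5, 50.7, 59.6, 53.4, 58.1),
    "Dara"          = c(59.7, 48.0, 53.0, 64.2, 52.8, 44.4),
    "Gorchie"       = c(45.9, 42.0, 65.8, 63.8, 46.3, 32.1),
    "Hawassa Zuria" = c(40.2, 37.8, 30.3, 59.8, 41.2, 51.3),
    "Hulla"         = c(35.9, 39.9, 94.4, 129.2, 111.1, 107.1),
    "Loka Abaya"    = c(94.7, 61.2, 55.8, 64.9, 40.3, 63.7),
    "Malga"         = c(71.4, 99.2, 115.7, 106.7, 76.3, 85.9),
    "Shebedino"     = c(55.3, 60.9, 77.3, 90.6, 62.6, 79.3),
    "Wonsho"        = c(44.2, 20.8, 55.6, 52.9, 50.1, 60.9),
    "Wondogenet"    = c(32.0, 40.9, 56.1, 63.8, 79.9, 75.8)
  )
  colnames(t1) <- years
  table1 <- data.frame(district = rownames(t1), t1, check.names = FALSE,
                       row.names = NULL)
  attr(table1, "printed_average") <- c(52.6, 48.9, 62.3, 66.6, 52.5, 58.6)

  table2 <- data.frame(
    district = c("Boricha", "Malga", "Hulla", "Aleta Wondo", "Shebedino",
                 "Loka Abaya", "Dale", "Wondogenet", "Aleta Chuko",
                 "Arbegona", "Dara", "Gorchie", "Wensho", "Bona", "Chirie",
                 "Hawassa Zuria", "Aroresa", "Bursa", "Bensa"),
    observed = c(29153, 11952, 13335, 16005, 19636, 7351, 17713, 10792,
                 10883, 8606, 9786, 6102, 5045, 6713, 6407, 6391, 6393,
                 3691, 6452),
    expected = c(17146.87, 7522.60, 8856.59, 12947.92, 16027.43, 6799.06,
                 16626.00, 10668.99, 11462.75, 9308.74, 10638.18, 7226.53,
                 6143.31, 8306.62, 8252.70, 8528.34, 11664.18, 7100.39,
                 17178.83),
    obs_over_exp = c(1.70, 1.59, 1.51, 1.24, 1.23, 1.08, 1.07, 1.01, 0.95,
                     0.92, 0.92, 0.84, 0.82, 0.81, 0.78, 0.75, 0.55, 0.52,
                     0.38),
    relative_risk = c(1.82, 1.63, 1.54, 1.26, 1.25, 1.08, 1.07, 1.01, 0.95,
                      0.92, 0.92, 0.84, 0.82, 0.80, 0.77, 0.74, 0.53, 0.51,
                      0.36)
  )

  table3 <- data.frame(
    rank = 1:7,
    district = c("Boricha", "Malga", "Hulla", "Shebedino", "Aleta Wondo",
                 "Dale", "Loka Abaya"),
    population = c(49076, 21530, 25348, 45872, 37058, 47585, 19459),
    lat = c(6.939005, 6.933700, 6.487117, 6.874400, 6.596820, 6.745428,
            6.694306),
    lon = c(38.253064, 38.562860, 38.522366, 38.441810, 38.422840,
            38.409888, 38.202427),
    observed = c(29153, 11952, 13335, 19636, 16005, 17713, 7351),
    expected = c(17146.87, 7522.60, 8856.59, 16027.43, 12947.92, 16626.00,
                 6799.06),
    annual_per_100k = c(9898.2, 9249.8, 8765.7, 7132.6, 7196.4, 6202.4,
                        6294.4),
    obs_over_exp = c(1.70, 1.59, 1.51, 1.23, 1.24, 1.07, 1.08),
    relative_risk = c(1.82, 1.65, 1.54, 1.25, 1.26, 1.07, 1.08),
    llr = c(3864.33, 1154.94, 1030.89, 413.94, 360.24, 37.97, 22.60),
    p_value = rep("<0.001", 7)
  )

  table4 <- data.frame(
    rank = 1:5,
    district = c("Malga", "Loka Abaya", "Bursa", "Gorchie", "Wensho"),
    population = c(21530, 19459, 20322, 20683, 17583),
    lat = c(6.933700, 6.694306, 6.590160, 6.876740, 6.749010),
    lon = c(38.562860, 38.202427, 38.606330, 38.584650, 38.517450),
    time_frame = c("2012/12/1 to 2015/5/31", "2012/1/1 to 2012/5/31",
                   "2011/12/1 to 2011/12/31", "2014/3/1 to 2014/4/30",
                   "2012/3/1 to 2012/3/31"),
    month_start = c(17L, 6L, 5L, 32L, 8L),
    month_end = c(46L, 10L, 5L, 33L, 8L),
    observed = c(6186, 900, 327, 479, 216),
    expected = c(3097.21, 441.07, 93.27, 199.43, 81.28),
    annual_per_100k = c(11627.8, 11879.4, 20410.6, 13983.0, 15471.9),
    obs_over_exp = c(2.00, 2.04, 3.51, 2.40, 2.66),
    relative_risk = c(2.03, 2.05, 3.51, 2.41, 2.66),
    llr = c(1214.67, 183.47, 176.61, 140.34, 76.44),
    p_value = rep("<0.001", 5)
  )

  temporal_cluster <- list(
    time_frame = "2013/12/1 to 2015/5/31",
    month_start = 29L, month_end = 46L,
    observed = 63683, expected = 50695.23,
    relative_risk = 1.37, llr = 2109.93, p_value = "<0.001"
  )

  list(
    table1 = table1, table2 = table2, table3 = table3, table4 = table4,
    temporal_cluster = temporal_cluster,
    total_cases = 202406,
    annual_rate_per_100k = 5822,
    growth_rate = 0.029,
    underfive_fraction = 0.156,
    trend = list(slope_per_month = 0.015, intercept = 4.27)
  )
}
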