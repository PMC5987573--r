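#' Location table
#'
#' Validates and classifies a table of geographic reporting units: one row per
#' administrative unit with a point location and the size of the population at
#' risk at the start of the study panel.
#'
#' @param df data.frame with columns `unit_id` (unique short key), `name`
#'   (free text), `lat`, `lon` (decimal degrees, WGS84 assumed) and
#'   `base_population` (persons at risk at panel start, > 0).
#' @return The validated data.frame with class `location_table`.
#' @export
location_table <- function(df) {
  req <- c("unit_id", "name", "lat", "lon", "base_population")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0L)
    stop("location table is missing column(s): ", paste(miss, collapse = ", "))
  df$unit_id <- as.character(df$unit_id)
  if (anyDuplicated(df$unit_id))
    stop("duplicate unit_id in location table: ",
         paste(unique(df$unit_id[duplicated(df$unit_id)]), collapse = ", "))
  if (any(!is.finite(df$lat)) || any(df$lat < -90 | df$lat > 90))
    stop("lat must be finite and in [-90, 90]")
  if (any(!is.finite(df$lon)) || any(df$lon < -180 | df$lon > 180))
    stop("lon must be finite and in [-180, 180]")
  if (any(!is.finite(df$base_population)) || any(df$base_population <= 0))
    stop("base_population must be positive")
  rownames(df) <- NULL
  class(df) <- c("location_table", "data.frame")
  df
}

#' Read a location table from CSV
#'
#' @param path CSV file with header `unit_id,name,lat,lon,base_population`.
#' @return A [location_table()].
#' @export
read_location_table <- function(path) {
  location_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

new_panel <- function(x, class, start_month, start_year) {
  stopifnot(is.matrix(x))
  if (is.null(rownames(x))) stop("panel matrix must have unit_id rownames")
  if (anyDuplicated(rownames(x))) stop("duplicate unit_id in panel rows")
  start_month <- as.integer(start_month)
  if (start_month < 1L || start_month > 12L)
    stop("start_month must be a calendar month in 1..12")
  structure(x, start_month = start_month, start_year = as.integer(start_year),
            class = class)
}

#' Case panel
#'
#' A complete rectangular panel of non-negative monthly case counts: one row
#' per unit, one column per month. Months are indexed 0-based from panel
#' start; column `j` of the matrix holds month index `j - 1`. The calendar
#' month and year of month index 0 are kept as metadata (`start_month`,
#' `start_year` attributes) for seasonal analysis.
#'
#' @param counts integer matrix (units x months) with unit_id rownames; all
#'   entries finite, non-negative whole numbers.
#' @param start_month calendar month (1-12) of month index 0. Default 7
#'   (a July-June fiscal-year panel).
#' @param start_year calendar year of month index 0.
#' @return matrix with class `case_panel`.
#' @export
case_panel <- function(counts, start_month = 7L, start_year = 2011L) {
  counts <- as.matrix(counts)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("case counts must be finite non-negative integers")
  storage.mode(counts) <- "double"
  colnames(counts) <- as.character(seq_len(ncol(counts)) - 1L)
  new_panel(counts, c("case_panel", "matrix"), start_month, start_year)
}

#' Population panel
#'
#' Person-time denominators (person-months) on the same (unit, month) index
#' as a [case_panel()]; all entries strictly positive.
#'
#' @inheritParams case_panel
#' @param person_time numeric matrix (units x months), all entries > 0.
#' @return matrix with class `population_panel`.
#' @export
population_panel <- function(person_time, start_month = 7L, start_year = 2011L) {
  person_time <- as.matrix(person_time)
  if (any(!is.finite(person_time)) || any(person_time <= 0))
    stop("person_time must be finite and strictly positive")
  colnames(person_time) <- as.character(seq_len(ncol(person_time)) - 1L)
  new_panel(person_time, c("population_panel", "matrix"), start_month, start_year)
}

#' @export
n_units <- function(panel) nrow(panel)

#' @export
n_months <- function(panel) ncol(panel)

#' Total cases in a panel
#' @param panel a [case_panel()].
#' @export
total_cases <- function(panel) sum(panel)

check_same_index <- function(cases, pop) {
  if (!identical(dim(cases), dim(pop)) ||
      !identical(rownames(cases), rownames(pop)))
    stop("case panel and population panel must share the same (unit, month) index")
  invisible(TRUE)
}

parse_month_index <- function(month) {
  m <- as.character(month)
  iso <- grepl("^\\d{4}-\\d{2}$", m)
  if (all(iso)) {
    yy <- as.integer(substr(m, 1, 4))
    mm <- as.integer(substr(m, 6, 7))
    if (any(mm < 1L | mm > 12L)) stop("month out of range in ISO yyyy-mm value")
    list(abs = yy * 12L + (mm - 1L), iso = TRUE, year = yy, month = mm)
  } else if (!any(iso) && all(grepl("^-?\\d+$", m))) {
    list(abs = as.integer(m), iso = FALSE, year = NA_integer_, month = NA_integer_)
  } else {
    stop("month column must be all ISO yyyy-mm or all integer indices")
  }
}

#' Read a monthly case panel from CSV
#'
#' Reads long-format records (`unit_id, month, count`), checks them against a
#' location table, and assembles the complete rectangular panel. `month` may
#' be an ISO `yyyy-mm` string or an integer index; either way months are
#' re-indexed 0-based from the earliest month present. Every (unit, month)
#' cell must be present exactly once: gaps are an error, never silently
#' filled.
#'
#' @param path CSV file with header `unit_id,month,count`.
#' @param locations a [location_table()]; the panel rows are its units, in
#'   its order.
#' @param start_month,start_year calendar anchoring of month index 0, used
#'   when `month` is an integer index (ignored for ISO months, which carry
#'   their own calendar).
#' @return A [case_panel()].
#' @export
read_case_panel <- function(path, locations, start_month = 7L, start_year = 2011L) {
  locations <- location_table(as.data.frame(locations))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("unit_id", "month", "count")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0L)
    stop("case panel CSV is missing column(s): ", paste(miss, collapse = ", "))
  df$unit_id <- as.character(df$unit_id)

  unknown <- setdiff(df$unit_id, locations$unit_id)
  if (length(unknown) > 0L)
    stop("unknown unit_id in case panel: ", paste(sort(unknown), collapse = ", "))
  if (any(!is.finite(df$count)) || any(df$count < 0))
    stop("negative or non-finite count in case panel")

  pm <- parse_month_index(df$month)
  m0 <- pm$abs - min(pm$abs)
  nm <- max(m0) + 1L

  key <- paste(df$unit_id, m0, sep = "\r")
  if (anyDuplicated(key)) {
    d <- strsplit(key[duplicated(key)][1L], "\r")[[1L]]
    stop("duplicate record for unit ", d[1L], ", month ", d[2L])
  }

  counts <- matrix(NA_real_, nrow = nrow(locations), ncol = nm,
                   dimnames = list(locations$unit_id, NULL))
  counts[cbind(match(df$unit_id, locations$unit_id), m0 + 1L)] <- df$count
  if (anyNA(counts)) {
    idx <- which(is.na(counts), arr.ind = TRUE)[1L, ]
    stop("missing cell in case panel: unit ", rownames(counts)[idx[1L]],
         ", month ", idx[2L] - 1L)
  }

  if (pm$iso) {
    first <- which.min(pm$abs)
    start_month <- pm$month[first]
    start_year <- pm$year[first]
  }
  case_panel(counts, start_month = start_month, start_year = start_year)
}

#' Write a case panel to long-format CSV
#'
#' Inverse of [read_case_panel()]: writes `unit_id,month,count` rows with
#' 0-based integer month indices. A read/write round trip is lossless for
#' counts and index.
#'
#' @param panel a [case_panel()].
#' @param path output CSV path.
#' @export
write_case_panel <- function(panel, path) {
  df <- data.frame(
    unit_id = rep(rownames(panel), times = ncol(panel)),
    month = rep(seq_len(ncol(panel)) - 1L, each = nrow(panel)),
    count = as.vector(panel)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Calendar month (1-12) for each month index of a panel
#' @param panel a panel object carrying a `start_month` attribute.
#' @return integer vector of length `n_months(panel)`.
#' @export
panel_calendar_months <- function(panel) {
  sm <- attr(panel, "start_month")
  ((sm - 1L + seq_len(ncol(panel)) - 1L) %% 12L) + 1L
}
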