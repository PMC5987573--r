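#' Scan configuration
#'
#' Tuning parameters for the scan statistic. Defaults follow the standard
#' retrospective discrete-Poisson setup: circular windows capped at 50% of
#' the population at risk, temporal windows capped at 50% of the study
#' period, 1-month time aggregation, 999 Monte Carlo replicates, and
#' scanning for high rates only.
#'
#' @param max_spatial_population_fraction spatial cap, in (0, 0.5].
#' @param max_temporal_fraction temporal cap as a fraction of the study
#'   period, in (0, 0.5].
#' @param time_aggregation temporal resolution in months (window endpoints
#'   snap to multiples of it); default 1.
#' @param n_replicates Monte Carlo replicates; 0 (no inference, p = NA) or
#'   >= 9. Default 999, giving a minimum attainable p of 0.001.
#' @param seed optional integer seed for the Monte Carlo draws.
#' @param high_rates_only scan only for excesses (default TRUE); FALSE scans
#'   two-sided.
#' @param distance_metric `"cartesian_degrees"` (Euclidean distance on raw
#'   lat/lon degrees — the standard Cartesian convention for zonal-scale
#'   point data) or `"great_circle"` (haversine metres).
#' @return list with class `scan_config`.
#' @export
scan_config <- function(max_spatial_population_fraction = 0.5,
                        max_temporal_fraction = 0.5,
                        time_aggregation = 1L,
                        n_replicates = 999L,
                        seed = NULL,
                        high_rates_only = TRUE,
                        distance_metric = c("cartesian_degrees", "great_circle")) {
  if (max_spatial_population_fraction <= 0 || max_spatial_population_fraction > 0.5)
    stop("max_spatial_population_fraction must be in (0, 0.5]")
  if (max_temporal_fraction <= 0 || max_temporal_fraction > 0.5)
    stop("max_temporal_fraction must be in (0, 0.5]")
  n_replicates <- as.integer(n_replicates)
  if (n_replicates != 0L && n_replicates < 9L)
    stop("n_replicates must be 0 (no inference) or at least 9")
  time_aggregation <- as.integer(time_aggregation)
  if (time_aggregation < 1L) stop("time_aggregation must be >= 1 month")
  structure(list(
    max_spatial_population_fraction = max_spatial_population_fraction,
    max_temporal_fraction = max_temporal_fraction,
    time_aggregation = time_aggregation,
    n_replicates = n_replicates,
    seed = seed,
    high_rates_only = isTRUE(high_rates_only),
    distance_metric = match.arg(distance_metric)
  ), class = "scan_config")
}

unit_distance_matrix <- function(locations, metric) {
  if (metric == "great_circle") {
    d <- geosphere::distm(cbind(locations$lon, locations$lat),
                          fun = geosphere::distHaversine)
  } else {
    d <- as.matrix(stats::dist(cbind(locations$lat, locations$lon)))
  }
  dimnames(d) <- list(locations$unit_id, locations$unit_id)
  d
}

new_window_set <- function(kind, unit_ids, bases, base_center, base_radius,
                           intervals) {
  structure(list(kind = kind, unit_ids = unit_ids, bases = bases,
                 base_center = base_center, base_radius = base_radius,
                 intervals = intervals),
            class = "window_set")
}

#' @export
length.window_set <- function(x) nrow(x$intervals)

#' @export
print.window_set <- function(x, ...) {
  cat("<window_set>", x$kind, "-", length(x$bases), "member set(s),",
      nrow(x$intervals), "window(s)\n")
  invisible(x)
}

#' Member units of every window in a window set
#' @param ws a `window_set`.
#' @return list of character vectors (one per window, in window order).
#' @export
window_members <- function(ws) {
  lapply(ws$intervals$base, function(b) ws$unit_ids[ws$bases[[b]]])
}

# circles of k nearest neighbours around each centre; distance ties enter as
# a block (never split), ordered within block by unit_id. Returns deduplicated
# member sets with centre and radius.
nearest_neighbour_bases <- function(locations, dmat, unit_pt, cap_pt = Inf) {
  n <- nrow(locations)
  bases <- list(); centers <- integer(); radii <- numeric()
  seen <- character()
  for (ctr in seq_len(n)) {
    d <- dmat[ctr, ]
    ord <- order(d, locations$unit_id)
    dv <- d[ord]
    members <- integer(0)
    cum <- 0
    i <- 1L
    while (i <= n) {
      block <- which(dv == dv[i])        # tie block at this distance
      block <- block[block >= i]
      add <- ord[block]
      if (cum + sum(unit_pt[add]) > cap_pt * (1 + 1e-9)) break
      members <- c(members, add)
      cum <- cum + sum(unit_pt[add])
      key <- paste(sort(members), collapse = ",")
      if (!(key %in% seen)) {
        seen <- c(seen, key)
        bases[[length(bases) + 1L]] <- sort(members)
        centers <- c(centers, ctr)
        radii <- c(radii, dv[max(block)])
      }
      i <- max(block) + 1L
    }
  }
  list(bases = bases, centers = centers, radii = radii)
}

#' Enumerate circular spatial windows
#'
#' For every unit taken as a centre, grows a circle over its nearest
#' neighbours (the centre first; distance ties enter together), stopping
#' before the member person-time would exceed the configured fraction of
#' total person-time. Duplicate member sets arising from different centres
#' are kept once. Each spatial window spans the full study period.
#'
#' @param locations a [location_table()].
#' @param pop a [population_panel()] (rows must match `locations$unit_id`).
#' @param config a [scan_config()].
#' @return A `window_set` of kind `"spatial"`.
#' @export
enumerate_spatial_windows <- function(locations, pop, config) {
  locations <- location_table(as.data.frame(locations))
  if (!identical(locations$unit_id, rownames(pop)))
    stop("population panel rows must match the location table")
  dmat <- unit_distance_matrix(locations, config$distance_metric)
  unit_pt <- rowSums(pop)
  nn <- nearest_neighbour_bases(locations, dmat, unit_pt,
                                cap_pt = config$max_spatial_population_fraction * sum(unit_pt))
  nw <- length(nn$bases)
  intervals <- data.frame(base = seq_len(nw),
                          start = rep(0L, nw),
                          end = rep(ncol(pop) - 1L, nw))
  new_window_set("spatial", locations$unit_id, nn$bases, nn$centers,
                 nn$radii, intervals)
}

admissible_ranges <- function(n_months, max_fraction, aggregation = 1L) {
  max_len <- floor(max_fraction * n_months)
  max_len <- max_len - (max_len %% aggregation)
  if (max_len < 1L)
    stop("no admissible temporal window: cap of ", max_fraction,
         " over ", n_months, " months allows no interval")
  starts <- seq(0L, n_months - 1L, by = aggregation)
  out <- do.call(rbind, lapply(starts, function(s) {
    ends <- seq(s + aggregation - 1L, min(s + max_len - 1L, n_months - 1L),
                by = aggregation)
    cbind(start = s, end = ends)
  }))
  as.data.frame(out)
}

#' Enumerate temporal windows
#'
#' All inclusive month intervals \[s, e\] no longer than the temporal cap
#' (floor of cap x study length), at the configured aggregation, each
#' spanning every unit.
#'
#' @param n_months study length in months, >= 2.
#' @param config a [scan_config()].
#' @param unit_ids unit universe (needed so the windows carry their member
#'   set); defaults to a placeholder single unit.
#' @return A `window_set` of kind `"temporal"`.
#' @export
enumerate_temporal_windows <- function(n_months, config, unit_ids = "all") {
  n_months <- as.integer(n_months)
  if (n_months < 2L) stop("need at least 2 months")
  rng <- admissible_ranges(n_months, config$max_temporal_fraction,
                           config$time_aggregation)
  intervals <- data.frame(base = 1L, start = rng$start, end = rng$end)
  new_window_set("temporal", unit_ids, list(seq_along(unit_ids)),
                 NA_integer_, NA_real_, intervals)
}

#' Enumerate space-time cylinders
#'
#' The cross product of candidate circular bases (nearest-neighbour circles
#' around every centre) and admissible temporal ranges, keeping a cylinder
#' when its interval respects the temporal cap and its person-time does not
#' exceed the spatial cap's fraction of total person-time over the same
#' interval.
#'
#' @inheritParams enumerate_spatial_windows
#' @param n_months study length in months.
#' @return A `window_set` of kind `"spacetime"`.
#' @export
enumerate_spacetime_windows <- function(locations, pop, n_months, config) {
  locations <- location_table(as.data.frame(locations))
  if (!identical(locations$unit_id, rownames(pop)))
    stop("population panel rows must match the location table")
  n_months <- as.integer(n_months)
  dmat <- unit_distance_matrix(locations, config$distance_metric)
  nn <- nearest_neighbour_bases(locations, dmat, rowSums(pop), cap_pt = Inf)
  rng <- admissible_ranges(n_months, config$max_temporal_fraction,
                           config$time_aggregation)

  # person-time of each base over each candidate interval, via cumulatives
  nb <- length(nn$bases)
  B <- matrix(0, nb, nrow(pop))
  for (i in seq_len(nb)) B[i, nn$bases[[i]]] <- 1
  cs_base <- cbind(0, t(apply(B %*% unclass(pop), 1L, cumsum)))
  cs_tot <- c(0, cumsum(colSums(pop)))

  base_idx <- rep(seq_len(nb), each = nrow(rng))
  s <- rep(rng$start, times = nb)
  e <- rep(rng$end, times = nb)
  pt_win <- cs_base[cbind(base_idx, e + 2L)] - cs_base[cbind(base_idx, s + 1L)]
  pt_int <- cs_tot[e + 2L] - cs_tot[s + 1L]
  keep <- pt_win <= config$max_spatial_population_fraction * pt_int * (1 + 1e-9)

  used <- sort(unique(base_idx[keep]))
  remap <- match(base_idx[keep], used)
  intervals <- data.frame(base = remap, start = s[keep], end = e[keep])
  new_window_set("spacetime", locations$unit_id, nn$bases[used],
                 nn$centers[used], nn$radii[used], intervals)
}
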