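# Independent brute-force scan oracle for small panels.
#
# Enumerates every admissible window by direct looping — k-nearest circles
# around each centre for the spatial base, every month interval up to the
# temporal cap — and evaluates the Poisson window likelihood ratio straight
# from its definition, c*log(c/E) + (C-c)*log((C-c)/(C-E)) for c > E.
# Shares no code with the package's vectorized scan engine.

oracle_windows <- function(locations, cases, pop, mode,
                           frac_s = 0.5, frac_t = 0.5) {
  U <- nrow(cases); M <- ncol(cases)
  C <- sum(cases); P <- sum(pop)

  sets <- list()
  if (mode == "temporal") {
    sets <- list(seq_len(U))
  } else {
    seen <- character()
    for (ctr in seq_len(U)) {
      d <- sqrt((locations$lat - locations$lat[ctr])^2 +
                (locations$lon - locations$lon[ctr])^2)
      ord <- order(d, locations$unit_id)
      for (k in seq_len(U)) {
        s <- sort(ord[seq_len(k)])
        key <- paste(s, collapse = ",")
        if (!(key %in% seen)) { seen <- c(seen, key); sets[[length(sets) + 1L]] <- s }
      }
    }
  }

  if (mode == "spatial") {
    intervals <- matrix(c(0L, M - 1L), 1L)
  } else {
    maxlen <- floor(frac_t * M)
    intervals <- NULL
    for (s in 0:(M - 1L)) for (e in s:(M - 1L))
      if (e - s + 1L <= maxlen) intervals <- rbind(intervals, c(s, e))
  }

  rows <- list()
  for (si in seq_along(sets)) {
    set <- sets[[si]]
    for (r in seq_len(nrow(intervals))) {
      cols <- (intervals[r, 1L]:intervals[r, 2L]) + 1L
      pt_win <- sum(pop[set, cols])
      pt_all <- sum(pop[, cols])
      if (mode != "temporal" && pt_win > frac_s * pt_all * (1 + 1e-9)) next
      c_w <- sum(cases[set, cols])
      e_w <- pt_win * C / P
      llr <- if (c_w > e_w)
        c_w * log(c_w / e_w) + (C - c_w) * log((C - c_w) / (C - e_w)) else 0
      rows[[length(rows) + 1L]] <- list(
        key = paste(rownames(cases)[set], collapse = ","),
        start = intervals[r, 1L], end = intervals[r, 2L],
        c = c_w, e = e_w, llr = llr)
    }
  }
  do.call(rbind, lapply(rows, as.data.frame))
}

# small random panel on random coordinates; occasionally plants a hot region
random_small_panel <- function(n_units = 5L, n_months = 12L) {
  ids <- paste0("u", seq_len(n_units))
  loc <- location_table(data.frame(
    unit_id = ids, name = ids,
    lat = runif(n_units, 6, 7), lon = runif(n_units, 38, 39),
    base_population = runif(n_units, 500, 3000)))
  pt <- matrix(runif(n_units * n_months, 300, 2000), n_units,
               dimnames = list(ids, NULL))
  lambda <- pt * 0.01
  if (runif(1) < 0.5) {
    u <- sample(n_units, 1L); m <- sort(sample(n_months, 2L))
    lambda[u, m[1L]:m[2L]] <- lambda[u, m[1L]:m[2L]] * runif(1, 1.5, 3)
  }
  counts <- matrix(rpois(length(lambda), lambda), n_units,
                   dimnames = list(ids, NULL))
  counts[1L, 1L] <- counts[1L, 1L] + 1L   # guarantee a non-empty panel
  list(locations = loc,
       cases = case_panel(counts),
       pop = population_panel(pt))
}

# convenience: equal-population location table on given coordinates
grid_locations <- function(lat, lon, pop = 1000) {
  ids <- LETTERS[seq_along(lat)]
  location_table(data.frame(unit_id = ids, name = ids, lat = lat, lon = lon,
                            base_population = rep(pop, length(lat))))
}
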