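C0 <- 202406

test_that("Poisson window LLR matches published cluster statistics", {
  expect_equal(poisson_llr(29153, 17146.87, C0), 3864.33, tolerance = 0.5 / 3864)
  expect_equal(poisson_llr(6186, 3097.21, C0), 1214.67, tolerance = 0.5 / 1214)
  expect_equal(poisson_llr(327, 93.27, C0), 176.61, tolerance = 0.5 / 176)
  expect_equal(poisson_llr(63683, 50695.23, C0), 2109.93, tolerance = 0.5 / 2109)
  expect_equal(poisson_llr(1500, 1500, C0), 0)
  expect_equal(poisson_llr(100, 200, C0), 0)       # deficit, high-rate indicator
  expect_gt(poisson_llr(100, 200, C0, high_rates_only = FALSE), 0)
  expect_equal(poisson_llr(0, 50, C0), 0)
  expect_error(poisson_llr(10, 0, C0), "positive")
  expect_error(poisson_llr(-1, 5, C0), "\\[0, total_cases\\]")
})

test_that("LLR is strictly increasing in the observed count above its expectation", {
  E <- 350.5
  c <- seq(351, 2000, by = 7)
  llr <- poisson_llr(c, E, C0)
  expect_true(all(diff(llr) > 0))
})

test_that("window relative risk uses the outside-window baseline", {
  expect_equal(window_relative_risk(29153, 17146.87, C0), 1.82, tolerance = 0.01 / 1.82)
  expect_equal(window_relative_risk(63683, 50695.23, C0), 1.37, tolerance = 0.01 / 1.37)
  expect_equal(window_relative_risk(6186, 3097.21, C0), 2.03, tolerance = 0.01 / 2.03)
  expect_equal(window_relative_risk(327, 93.27, C0), 3.51, tolerance = 0.01 / 3.51)
  expect_equal(window_relative_risk(500, 500, C0), 1)
  expect_error(window_relative_risk(C0, 100, C0), "all cases")
})

test_that("spatial window enumeration grows nearest-neighbour circles under the cap", {
  # three collinear equal-population units: any 2-unit window already holds
  # 2/3 of the person-time, so under a 50% cap only singletons are admissible
  locs <- grid_locations(lat = c(6.0, 6.5, 7.0), lon = rep(38, 3))
  pop <- population_panel(matrix(100, 3, 4, dimnames = list(locs$unit_id, NULL)))
  ws <- enumerate_spatial_windows(locs, pop, scan_config())
  keys <- sort(vapply(ws$bases, function(b) paste(locs$unit_id[b], collapse = ","),
                      character(1)))
  expect_equal(keys, c("A", "B", "C"))
  # with unequal populations a neighbour that fits under the cap is absorbed
  locs2 <- location_table(data.frame(unit_id = c("A", "B", "C"),
                                     name = c("A", "B", "C"),
                                     lat = c(6.0, 6.1, 7.0), lon = rep(38, 3),
                                     base_population = c(200, 100, 700)))
  pop2 <- population_panel(matrix(rep(c(200, 100, 700), 4), 3,
                                  dimnames = list(c("A", "B", "C"), NULL)))
  ws2 <- enumerate_spatial_windows(locs2, pop2, scan_config())
  keys2 <- sort(vapply(ws2$bases, function(b) paste(locs2$unit_id[b], collapse = ","),
                       character(1)))
  # C alone holds 70% of person-time: no admissible window centred there
  expect_equal(keys2, c("A", "A,B", "B"))

  # 19 equal units: maximum circle holds floor(0.5 * 19) = 9 members
  set.seed(41)
  locs19 <- grid_locations(lat = runif(19, 6, 7), lon = runif(19, 38, 39))
  pop19 <- population_panel(matrix(100, 19, 2, dimnames = list(locs19$unit_id, NULL)))
  ws19 <- enumerate_spatial_windows(locs19, pop19, scan_config())
  expect_equal(max(lengths(ws19$bases)), 9L)
  # every singleton is a candidate window
  singles <- vapply(ws19$bases[lengths(ws19$bases) == 1L],
                    function(b) locs19$unit_id[b], character(1))
  expect_setequal(singles, locs19$unit_id)

  # a lone unit always exceeds a 0.5 cap: no admissible window
  ws1 <- enumerate_spatial_windows(locs[1L, ], population_panel(
    matrix(100, 1, 4, dimnames = list("A", NULL))), scan_config())
  expect_length(ws1, 0L)
})

test_that("temporal window enumeration respects the study-period cap", {
  cfg <- scan_config()
  ws <- enumerate_temporal_windows(4, cfg)
  expect_equal(length(ws), 7L)  # 4 singles + 3 pairs
  expect_true(all(ws$intervals$end - ws$intervals$start + 1L <= 2L))

  ws72 <- enumerate_temporal_windows(72, cfg)
  lens <- ws72$intervals$end - ws72$intervals$start + 1L
  expect_equal(max(lens), 36L)
  # the published 18-month December 2013 - May 2015 interval is admissible
  expect_true(any(ws72$intervals$start == 29L & ws72$intervals$end == 46L))

  expect_error(enumerate_temporal_windows(12, scan_config(max_temporal_fraction = 0.05)),
               "no admissible temporal window")
})

test_that("space-time cylinders cross admissible bases with admissible intervals", {
  locs <- grid_locations(lat = c(6.2, 6.8), lon = c(38.1, 38.7))
  pop <- population_panel(matrix(100, 2, 2, dimnames = list(locs$unit_id, NULL)))
  ws <- enumerate_spacetime_windows(locs, pop, 2, scan_config())
  expect_equal(length(ws), 4L)  # each single unit x each single month
  expect_true(all(lengths(ws$bases) == 1L))

  # a 30-month cylinder fits under the 36-month cap of a 72-month panel
  pop72 <- population_panel(matrix(100, 2, 72, dimnames = list(locs$unit_id, NULL)))
  ws72 <- enumerate_spacetime_windows(locs, pop72, 72, scan_config())
  expect_true(any(ws72$intervals$start == 17L & ws72$intervals$end == 46L))
})

test_that("scan agrees with a brute-force enumerator on a hand-checkable panel", {
  set.seed(42)
  p <- random_small_panel()
  cfg <- scan_config(n_replicates = 0L)
  for (mode in c("spatial", "temporal", "spacetime")) {
    ws <- switch(mode,
      spatial = enumerate_spatial_windows(p$locations, p$pop, cfg),
      temporal = enumerate_temporal_windows(ncol(p$cases), cfg,
                                            unit_ids = rownames(p$cases)),
      spacetime = enumerate_spacetime_windows(p$locations, p$pop,
                                              ncol(p$cases), cfg))
    res <- scan(p$cases, p$pop, ws, cfg)
    ora <- oracle_windows(p$locations, p$cases, p$pop, mode)
    expect_equal(res$llr[1L], max(ora$llr), tolerance = 1e-10)
    arg <- ora[ora$llr >= max(ora$llr) - 1e-9, ]
    hit <- any(arg$key == res$unit_label[1L] &
               arg$start == res$month_start[1L] &
               arg$end == res$month_end[1L])
    expect_true(hit, label = paste("top", mode, "window found by oracle"))
  }
})

test_that("LLR surface is invariant to rescaling all person-time", {
  set.seed(43)
  p <- random_small_panel()
  cfg <- scan_config(n_replicates = 0L)
  ws <- enumerate_spatial_windows(p$locations, p$pop, cfg)
  res1 <- scan(p$cases, p$pop, ws, cfg)
  pop2 <- population_panel(unclass(p$pop) * 12.3)
  res2 <- scan(p$cases, pop2, enumerate_spatial_windows(p$locations, pop2, cfg), cfg)
  expect_equal(res2$llr, res1$llr)
  expect_equal(res2$unit_label, res1$unit_label)
})

test_that("Monte Carlo p-values live on the achievable grid and are reproducible", {
  set.seed(44)
  p <- random_small_panel()
  cfg <- scan_config(n_replicates = 99L, seed = 9L)
  ws <- enumerate_spatial_windows(p$locations, p$pop, cfg)
  res <- scan(p$cases, p$pop, ws, cfg)
  expect_true(all(res$p_value >= 1 / 100 & res$p_value <= 1))
  expect_true(all(abs(res$p_value * 100 - round(res$p_value * 100)) < 1e-9))
  res2 <- scan(p$cases, p$pop, ws, cfg)
  expect_identical(res$p_value, res2$p_value)
  expect_error(scan(case_panel(matrix(0, nrow(p$cases), ncol(p$cases),
                                      dimnames = dimnames(p$cases))),
                    p$pop, ws, cfg), "no cases")
})

test_that("cluster reporting is greedy, disjoint and significance-filtered", {
  set.seed(45)
  cfg <- scan_config(n_replicates = 99L, seed = 5L)
  sim <- generate_panel(generator_config(
    n_units = 8L, n_months = 24L, base_rate = 0.01,
    seasonal_indices = rep(1, 12), trend_per_month = 0,
    planted = list(planted_cluster(rr = 3, units = "U01"),
                   planted_cluster(rr = 3, units = "U05")),
    seed = 45))
  ws <- enumerate_spatial_windows(sim$locations, sim$population, cfg)
  res <- scan(sim$cases, sim$population, ws, cfg)
  rep <- report_clusters(res, alpha = 0.05)
  expect_equal(rep$rank, seq_len(nrow(rep)))
  expect_true(all(diff(rep$llr) <= 0))
  expect_true(all(rep$p_value < 0.05))
  # pairwise disjoint member sets
  for (i in seq_len(nrow(rep))) for (j in seq_len(i - 1L))
    expect_length(intersect(rep$units[[i]], rep$units[[j]]), 0L)
  # of all windows sharing a unit, only the highest-LLR one is reported
  in_u01 <- vapply(res$units, function(u) "U01" %in% u, logical(1))
  rep_u01 <- vapply(rep$units, function(u) "U01" %in% u, logical(1))
  expect_equal(sum(rep_u01), 1L)
  expect_equal(rep$llr[rep_u01], max(res$llr[in_u01]))
})

test_that("temporal secondary clusters never share months with higher ranks", {
  set.seed(46)
  sim <- generate_panel(generator_config(
    n_units = 5L, n_months = 48L, base_rate = 0.01,
    seasonal_indices = rep(1, 12), trend_per_month = 0,
    planted = list(planted_cluster(rr = 2.5, month_start = 10L, month_end = 14L),
                   planted_cluster(rr = 2.0, month_start = 30L, month_end = 33L)),
    seed = 46))
  cfg <- scan_config(n_replicates = 99L, seed = 6L)
  ws <- enumerate_temporal_windows(48, cfg, unit_ids = rownames(sim$cases))
  rep <- report_clusters(scan(sim$cases, sim$population, ws, cfg))
  if (nrow(rep) > 1L) {
    for (i in 2:nrow(rep)) for (j in 1:(i - 1L))
      expect_true(rep$month_start[i] > rep$month_end[j] ||
                  rep$month_end[i] < rep$month_start[j])
  }
  expect_gte(nrow(rep), 1L)
})
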