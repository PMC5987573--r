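test_that("location table validation catches bad keys and coordinates", {
  df <- data.frame(unit_id = c("a", "b"), name = c("A", "B"),
                   lat = c(6.5, 7.0), lon = c(38.1, 38.9),
                   base_population = c(100, 200))
  expect_s3_class(location_table(df), "location_table")
  expect_error(location_table(df[, -2]), "missing column")
  expect_error(location_table(transform(df, unit_id = c("a", "a"))), "duplicate")
  expect_error(location_table(transform(df, lat = c(95, 7))), "lat")
  expect_error(location_table(transform(df, base_population = c(0, 1))),
               "base_population")
})

make_panel_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE)
  path
}

three_locs <- grid_locations(lat = c(6.5, 6.6, 6.7), lon = c(38.1, 38.2, 38.3))

test_that("case panel CSV reading builds a complete 0-based panel", {
  df <- expand.grid(unit_id = c("A", "B", "C"), month = 0:3)
  df$count <- seq_len(nrow(df))
  panel <- read_case_panel(make_panel_csv(df), three_locs)
  expect_equal(dim(panel), c(3L, 4L))
  expect_equal(total_cases(panel), sum(df$count))
  expect_equal(rownames(panel), c("A", "B", "C"))
})

test_that("ISO months are re-indexed from the earliest and anchor the calendar", {
  df <- expand.grid(unit_id = c("A", "B", "C"),
                    month = c("2011-07", "2011-08", "2011-09"))
  df$count <- 1
  panel <- read_case_panel(make_panel_csv(df), three_locs)
  expect_equal(ncol(panel), 3L)
  expect_equal(attr(panel, "start_month"), 7L)
  expect_equal(attr(panel, "start_year"), 2011L)
  expect_equal(panel_calendar_months(panel), c(7L, 8L, 9L))
})

test_that("malformed panels fail loudly, naming the offending cell", {
  df <- expand.grid(unit_id = c("A", "B", "C"), month = 0:3)
  df$count <- 1
  expect_error(read_case_panel(make_panel_csv(df[-5L, ]), three_locs),
               "missing cell.*unit B, month 1")
  expect_error(read_case_panel(make_panel_csv(rbind(df, df[1L, ])), three_locs),
               "duplicate record")
  bad <- transform(df, unit_id = as.character(unit_id))
  bad$unit_id[2L] <- "Z"
  expect_error(read_case_panel(make_panel_csv(bad), three_locs),
               "unknown unit_id.*Z")
  neg <- df; neg$count[3L] <- -1
  expect_error(read_case_panel(make_panel_csv(neg), three_locs), "negative")
})

test_that("case panel CSV write/read round trip is lossless", {
  set.seed(11)
  counts <- matrix(rpois(12, 5), 3, dimnames = list(c("A", "B", "C"), NULL))
  panel <- case_panel(counts)
  path <- tempfile(fileext = ".csv")
  write_case_panel(panel, path)
  back <- read_case_panel(path, three_locs)
  expect_equal(unclass(back)[, ], unclass(panel)[, ])
})

test_that("district totals read as an aggregated one-month panel give the zone total", {
  tabs <- sidama_tables()
  locs <- location_table(data.frame(
    unit_id = tabs$table2$district, name = tabs$table2$district,
    lat = 6.5, lon = 38.5, base_population = 1000))
  df <- data.frame(unit_id = tabs$table2$district, month = 0L,
                   count = tabs$table2$observed)
  panel <- read_case_panel(make_panel_csv(df), locs)
  expect_equal(total_cases(panel), 202406)
  expect_equal(total_cases(panel), tabs$total_cases)
})

test_that("published excess-risk table is internally consistent", {
  t2 <- sidama_tables()$table2
  expect_equal(nrow(t2), 19L)
  # printed ratio column follows from the printed observed and expected
  expect_true(all(abs(t2$observed / t2$expected - t2$obs_over_exp) <= 0.005 + 1e-9))
  # expected counts are normalized to the case total
  expect_lt(abs(sum(t2$expected) - 202406) / 202406, 0.001)
})

test_that("cluster GeoJSON export writes one ranked feature per cluster", {
  t3 <- sidama_tables()$table3
  locs <- location_table(data.frame(
    unit_id = t3$district, name = t3$district, lat = t3$lat, lon = t3$lon,
    base_population = t3$population))
  results <- data.frame(
    rank = t3$rank, kind = "spatial", unit_label = t3$district,
    center_unit = t3$district, radius = 0,
    month_start = 0L, month_end = 71L,
    observed = t3$observed, expected = t3$expected,
    obs_over_exp = t3$obs_over_exp, relative_risk = t3$relative_risk,
    llr = t3$llr, p_value = 0.001)
  results$units <- I(as.list(t3$district))
  path <- tempfile(fileext = ".geojson")
  write_clusters_geojson(results, locs, path)
  gj <- jsonlite::read_json(path)
  expect_equal(gj$type, "FeatureCollection")
  expect_length(gj$features, 7L)
  expect_equal(vapply(gj$features, function(f) f$properties$rank, numeric(1)),
               1:7)
  f1 <- gj$features[[1L]]
  expect_equal(f1$geometry$type, "Point")
  # RFC 7946 lon-lat order
  expect_equal(unlist(f1$geometry$coordinates), c(t3$lon[1L], t3$lat[1L]))
  expect_equal(f1$properties$observed, 29153)
  expect_equal(f1$properties$llr, t3$llr[1L])

  empty <- results[0L, ]
  write_clusters_geojson(empty, locs, path)
  expect_length(jsonlite::read_json(path)$features, 0L)

  bad <- results[1L, ]; bad$units <- I(list("Nowhere"))
  expect_error(write_clusters_geojson(bad, locs, path), "Nowhere")
})
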