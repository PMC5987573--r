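#' Export clusters as a GeoJSON FeatureCollection
#'
#' Writes one Feature per cluster row, RFC 7946 compliant (WGS84, lon-lat
#' coordinate order): a Point at the unit's location for single-unit
#' windows, a MultiPoint over the member units otherwise. All cluster fields
#' (rank if present, kind, member units, month range, observed, expected,
#' observed/expected, relative risk, LLR, Monte Carlo p) are carried as
#' Feature properties, along with the window's centre unit and radius.
#' An empty result table yields a valid empty FeatureCollection.
#'
#' @param results a `cluster_results` table from [scan()] or
#'   [report_clusters()].
#' @param locations a [location_table()] containing every member unit.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_clusters_geojson <- function(results, locations, path) {
  locations <- location_table(as.data.frame(locations))
  features <- lapply(seq_len(nrow(results)), function(i) {
    units <- results$units[[i]]
    miss <- setdiff(units, locations$unit_id)
    if (length(miss) > 0L)
      stop("cluster unit(s) not in location table: ", paste(miss, collapse = ", "))
    li <- match(units, locations$unit_id)
    coords <- cbind(locations$lon[li], locations$lat[li])
    geometry <- if (length(units) == 1L)
      list(type = "Point", coordinates = c(coords[1L, 1L], coords[1L, 2L]))
    else
      list(type = "MultiPoint", coordinates = coords)
    props <- list(
      kind = results$kind[i],
      units = paste(units, collapse = ","),
      center_unit = results$center_unit[i],
      radius = results$radius[i],
      month_start = results$month_start[i],
      month_end = results$month_end[i],
      observed = results$observed[i],
      expected = results$expected[i],
      obs_over_exp = results$obs_over_exp[i],
      relative_risk = results$relative_risk[i],
      llr = results$llr[i],
      p_value = results$p_value[i]
    )
    if ("rank" %in% names(results)) props <- c(list(rank = results$rank[i]), props)
    list(type = "Feature", geometry = geometry, properties = props)
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(path)
}
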