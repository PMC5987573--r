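row_cumsum0 <- function(M) {
  # nb x (m+1): leading zero column, so sum over months s..e (0-based) is
  # CS[, e + 2] - CS[, s + 1]
  if (nrow(M) == 1L) matrix(c(0, cumsum(M[1L, ])), 1L)
  else cbind(0, t(apply(M, 1L, cumsum)))
}

window_stats <- function(Bmat, M, tab) {
  CS <- row_cumsum0(Bmat %*% M)
  CS[cbind(tab$base, tab$end + 2L)] - CS[cbind(tab$base, tab$start + 1L)]
}

#' Run the scan statistic over a set of windows
#'
#' Computes, for every candidate window, the observed count c, the expected
#' count E under proportional person-time (summed over exactly the window's
#' cells), and the Poisson window log-likelihood ratio; then evaluates Monte
#' Carlo significance by generating `n_replicates` datasets under the
#' conditional null (C cases redistributed multinomially with cell
#' probabilities E(cell)/C), scanning each over the same windows, and
#' ranking the observed LLRs among the replicate maxima:
#' p = (1 + number of replicate maxima >= LLR) / (1 + n_replicates).
#'
#' For spatial and space-time window sets the returned table keeps the
#' best-scoring window per distinct member set (the candidate-cluster
#' convention: any other interval on the same base can never be reported
#' ahead of it under a unit-overlap rule); temporal scans return every
#' interval. Rows are sorted by LLR descending, ties broken by fewer cells,
#' then lexicographic member label and start month.
#'
#' @param cases a [case_panel()] with at least one case.
#' @param pop a [population_panel()] on the same index.
#' @param windows a `window_set` from one of the `enumerate_*_windows()`
#'   functions (non-empty).
#' @param config a [scan_config()].
#' @return data.frame with class `cluster_results`: kind, units (list
#'   column), unit_label, center_unit, radius, month_start, month_end,
#'   n_cells, observed, expected, obs_over_exp, relative_risk, llr, p_value.
#'   Attributes: `total_cases`, `n_replicates`, `replicate_max` (the Monte
#'   Carlo maxima, for diagnostics).
#' @export
scan <- function(cases, pop, windows, config = scan_config()) {
  check_same_index(cases, pop)
  if (!inherits(windows, "window_set")) stop("windows must be a window_set")
  if (length(windows) == 0L) stop("empty window set")
  C <- sum(cases)
  if (C <= 0) stop("case panel contains no cases")
  if (windows$kind != "temporal" &&
      !identical(windows$unit_ids, rownames(cases)))
    stop("window set was enumerated for different units than the panel")

  E <- expected_counts(cases, pop)
  tab <- windows$intervals
  nu <- nrow(cases)
  if (windows$kind == "temporal") {
    # a temporal window always spans every unit of the panel
    windows$unit_ids <- rownames(cases)
    windows$bases <- list(seq_len(nu))
  }
  nb <- length(windows$bases)
  Bmat <- matrix(0, nb, nu)
  for (i in seq_len(nb)) Bmat[i, windows$bases[[i]]] <- 1

  e_w <- window_stats(Bmat, E, tab)
  c_w <- window_stats(Bmat, unclass(cases), tab)
  llr_w <- poisson_llr(c_w, e_w, C, high_rates_only = config$high_rates_only)

  R <- config$n_replicates
  if (R > 0L) {
    if (!is.null(config$seed)) set.seed(config$seed)
    prob <- as.vector(E) / C
    maxima <- numeric(R)
    for (r in seq_len(R)) {
      cnt <- matrix(stats::rmultinom(1L, C, prob), nu)
      cr <- window_stats(Bmat, cnt, tab)
      if (config$high_rates_only) {
        hot <- which(cr > e_w)
        maxima[r] <- if (length(hot) == 0L) 0 else
          max(poisson_llr(cr[hot], e_w[hot], C, high_rates_only = FALSE))
      } else {
        maxima[r] <- max(poisson_llr(cr, e_w, C, high_rates_only = FALSE))
      }
    }
    sorted <- sort(maxima)
    n_ge <- R - findInterval(llr_w, sorted, left.open = TRUE)
    p_w <- (1 + n_ge) / (1 + R)
  } else {
    maxima <- numeric(0)
    p_w <- rep(NA_real_, length(llr_w))
  }

  base_size <- lengths(windows$bases)
  labels <- vapply(windows$bases,
                   function(b) paste(windows$unit_ids[b], collapse = ","),
                   character(1))
  n_cells <- base_size[tab$base] * (tab$end - tab$start + 1L)
  ord <- order(-llr_w, n_cells, labels[tab$base], tab$start)
  keep <- if (windows$kind == "temporal") ord else ord[!duplicated(tab$base[ord])]

  b <- tab$base[keep]
  out <- data.frame(
    kind = windows$kind,
    unit_label = labels[b],
    center_unit = ifelse(is.na(windows$base_center[b]), NA_character_,
                         windows$unit_ids[windows$base_center[b]]),
    radius = windows$base_radius[b],
    month_start = tab$start[keep],
    month_end = tab$end[keep],
    n_cells = n_cells[keep],
    observed = c_w[keep],
    expected = e_w[keep],
    obs_over_exp = c_w[keep] / e_w[keep],
    relative_risk = ifelse(c_w[keep] < C,
                           (c_w[keep] / e_w[keep]) /
                             ((C - c_w[keep]) / (C - e_w[keep])), Inf),
    llr = llr_w[keep],
    p_value = p_w[keep],
    stringsAsFactors = FALSE
  )
  out$units <- I(lapply(windows$bases[b], function(i) windows$unit_ids[i]))
  rownames(out) <- NULL
  structure(out, total_cases = C, n_replicates = R, replicate_max = maxima,
            class = c("cluster_results", "data.frame"))
}

ranges_overlap <- function(s1, e1, s2, e2) s1 <= e2 && s2 <= e1

#' Select primary and secondary clusters
#'
#' Greedy non-overlap reporting: walking the scan results in decreasing LLR
#' order, a window is reported if it is significant (Monte Carlo p below
#' `alpha`) and disjoint from every already-reported cluster — sharing no
#' member unit for spatial and space-time scans, no month for temporal
#' scans. The first reported cluster (maximal LLR) is the primary cluster,
#' rank 1; the rest are secondary clusters in rank order.
#'
#' @param results a `cluster_results` table from [scan()], sorted by LLR.
#' @param alpha significance threshold on the Monte Carlo p-value (default
#'   0.05); `NULL` to skip the significance filter (e.g. when the scan was
#'   run without replicates).
#' @return the reported subset of `results` with a leading `rank` column.
#' @export
report_clusters <- function(results, alpha = 0.05) {
  if (!inherits(results, "cluster_results")) stop("results must come from scan()")
  keep <- logical(nrow(results))
  for (i in seq_len(nrow(results))) {
    if (!is.null(alpha)) {
      p <- results$p_value[i]
      if (is.na(p) || p >= alpha) next
    }
    clash <- FALSE
    for (j in which(keep)) {
      if (results$kind[i] == "temporal") {
        clash <- ranges_overlap(results$month_start[i], results$month_end[i],
                                results$month_start[j], results$month_end[j])
      } else {
        clash <- length(intersect(results$units[[i]], results$units[[j]])) > 0L
      }
      if (clash) break
    }
    if (!clash) keep[i] <- TRUE
  }
  out <- results[keep, , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  class(out) <- c("cluster_results", "data.frame")
  out
}

#' @export
print.cluster_results <- function(x, ...) {
  df <- as.data.frame(x)
  df$units <- NULL
  df$expected <- round(df$expected, 2)
  df$obs_over_exp <- round(df$obs_over_exp, 2)
  df$relative_risk <- round(df$relative_risk, 2)
  df$llr <- round(df$llr, 2)
  print(utils::head(df, 10L))
  if (nrow(df) > 10L) cat("... and", nrow(df) - 10L, "more window(s)\n")
  invisible(x)
}
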