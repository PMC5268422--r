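#' Mann-Kendall trend test
#'
#' Nonparametric test for a monotonic trend in an ordered series. The
#' score is `S = sum_{i<j} sign(x_j - x_i)`; the reported correlation is
#' Kendall's tau-b (tie-corrected), and the two-sided p-value uses the
#' normal approximation with tie-adjusted variance and continuity
#' correction. The test is rank-based, so missing years may simply be
#' absent from the series: ordering matters, spacing does not.
#'
#' @param x numeric series ordered by time (length >= 3, no NAs).
#' @return Object of class `mk_test`: list with `tau`, `s_statistic`,
#'   `var_s`, `p_value`, `n`.
#' @export
mann_kendall <- function(x) {
  if (anyNA(x)) stop_domain("series contains NA; drop missing years first")
  n <- length(x)
  if (n < 3) stop_domain("Mann-Kendall test needs at least 3 values")
  d <- outer(x, x, "-")       # d[i, j] = x_i - x_j
  s <- -sum(sign(d[upper.tri(d)]))
  tie_sizes <- as.numeric(table(x))
  tie_sizes <- tie_sizes[tie_sizes > 1]
  n0 <- n * (n - 1) / 2
  n1 <- sum(tie_sizes * (tie_sizes - 1) / 2)
  denom <- sqrt((n0 - n1) * n0)    # no ties possible in the time index
  tau <- if (denom == 0) 0 else s / denom
  var_s <- (n * (n - 1) * (2 * n + 5) -
              sum(tie_sizes * (tie_sizes - 1) * (2 * tie_sizes + 5))) / 18
  if (var_s <= 0) {
    p <- 1
  } else {
    z <- if (s > 0) (s - 1) / sqrt(var_s)
         else if (s < 0) (s + 1) / sqrt(var_s)
         else 0
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  structure(list(tau = tau, s_statistic = as.integer(s), var_s = var_s,
                 p_value = p, n = n),
            class = "mk_test")
}

#' @export
print.mk_test <- function(x, ...) {
  cat(sprintf("Mann-Kendall: tau = %.3f, S = %d, p = %.4g, n = %d\n",
              x$tau, x$s_statistic, x$p_value, x$n))
  invisible(x)
}

#' Per-iteration Mann-Kendall trends of AOR index series
#'
#' For each Monte-Carlo iteration (and abundance measure), applies
#' [mann_kendall()] to the year series of each AOR index. Years in which
#' the regression failed (NA index) are dropped from that iteration's
#' series; iterations with fewer than 3 usable years are omitted with a
#' warning.
#'
#' @param iterations data.frame from [run_monte_carlo()] (columns
#'   `iteration`, `year`, `measure`, `slope`, `intercept`, `r_squared`).
#' @param indices which indices to test.
#' @return data.frame with columns `measure`, `index`, `iteration`, `tau`,
#'   `p_value`, `n_years`.
#' @export
iteration_trends <- function(iterations,
                             indices = c("slope", "intercept", "r_squared")) {
  stopifnot(all(c("iteration", "year", "measure") %in% names(iterations)))
  rows <- list()
  dropped <- 0L
  for (ms in unique(iterations$measure)) {
    sub <- iterations[iterations$measure == ms, ]
    for (it in unique(sub$iteration)) {
      ser <- sub[sub$iteration == it, ]
      ser <- ser[order(ser$year), ]
      for (idx in indices) {
        v <- ser[[idx]][!is.na(ser[[idx]])]
        if (length(v) < 3) {
          dropped <- dropped + 1L
          next
        }
        mk <- mann_kendall(v)
        rows[[length(rows) + 1L]] <-
          data.frame(measure = ms, index = idx, iteration = it,
                     tau = mk$tau, p_value = mk$p_value,
                     n_years = mk$n, stringsAsFactors = FALSE)
      }
    }
  }
  if (dropped > 0) {
    warning(dropped, " iteration series with < 3 usable years omitted",
            call. = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aggregate per-iteration trends into mean tau with confidence intervals
#'
#' Summarizes the Monte-Carlo distribution of Kendall's tau for each
#' (measure, index) group: the arithmetic mean tau-bar, a 95% interval,
#' and the fraction of iterations individually significant at p < 0.05. A
#' mean trend is declared significant when the interval excludes zero.
#' The default interval is the empirical percentile (2.5th/97.5th order
#' statistics of the tau sample); a normal-approximation interval is
#' available as an option.
#'
#' @param trends data.frame from [iteration_trends()] (columns `tau`,
#'   `p_value`, and optionally `measure`, `index`).
#' @param conf_level confidence level (default 0.95).
#' @param ci_method `"percentile"` (default) or `"normal"`.
#' @return data.frame of class `trend_summary` with columns `measure`,
#'   `index`, `mean_tau`, `ci_low`, `ci_high`, `significant`,
#'   `prop_significant`, `n_iterations`.
#' @export
aggregate_trends <- function(trends, conf_level = 0.95,
                             ci_method = c("percentile", "normal")) {
  ci_method <- match.arg(ci_method)
  if (!"measure" %in% names(trends)) trends$measure <- NA_character_
  if (!"index" %in% names(trends)) trends$index <- NA_character_
  groups <- unique(trends[c("measure", "index")])
  alpha <- 1 - conf_level
  rows <- vector("list", nrow(groups))
  for (i in seq_len(nrow(groups))) {
    g <- trends[(trends$measure %in% groups$measure[i]) &
                (trends$index %in% groups$index[i]), ]
    if (nrow(g) < 2) stop_domain("need at least 2 iterations to aggregate")
    taus <- g$tau
    if (ci_method == "percentile") {
      ci <- unname(stats::quantile(taus, c(alpha / 2, 1 - alpha / 2)))
    } else {
      se <- stats::sd(taus) / sqrt(length(taus))
      zq <- stats::qnorm(1 - alpha / 2)
      ci <- mean(taus) + c(-1, 1) * zq * se
    }
    rows[[i]] <- data.frame(
      measure = groups$measure[i], index = groups$index[i],
      mean_tau = mean(taus), ci_low = ci[1], ci_high = ci[2],
      significant = ci[1] > 0 || ci[2] < 0,
      prop_significant = mean(g$p_value < 0.05),
      n_iterations = nrow(g), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("trend_summary", "data.frame")
  out
}

#' Yearly mean and confidence band of simulated AOR indices
#'
#' Per (measure, year, index): mean across Monte-Carlo iterations and the
#' empirical percentile interval, the quantities plotted as a line with a
#' confidence ribbon. Years present in fewer than 2 iterations are
#' omitted with a warning.
#'
#' @param iterations data.frame from [run_monte_carlo()].
#' @param indices which indices to summarize.
#' @param conf_level confidence level (default 0.95).
#' @return data.frame with columns `measure`, `index`, `year`, `mean`,
#'   `ci_low`, `ci_high`, `n`.
#' @export
yearly_summary <- function(iterations,
                           indices = c("slope", "intercept", "r_squared"),
                           conf_level = 0.95) {
  alpha <- 1 - conf_level
  rows <- list()
  dropped <- 0L
  for (ms in unique(iterations$measure)) {
    sub <- iterations[iterations$measure == ms, ]
    for (yr in sort(unique(sub$year))) {
      ys <- sub[sub$year == yr, ]
      for (idx in indices) {
        v <- ys[[idx]][!is.na(ys[[idx]])]
        if (length(v) < 2) {
          dropped <- dropped + 1L
          next
        }
        q <- unname(stats::quantile(v, c(alpha / 2, 1 - alpha / 2)))
        rows[[length(rows) + 1L]] <-
          data.frame(measure = ms, index = idx, year = yr, mean = mean(v),
                     ci_low = q[1], ci_high = q[2], n = length(v),
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (dropped > 0) {
    warning(dropped, " year/index cells with < 2 iterations omitted",
            call. = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Empirical AOR trends straight from catch data
#'
#' Computes the yearly AOR regression directly on the observed per-tow
#' counts (no simulation): for each surveyed year of the region, the
#' species-by-tow matrix over the full roster is assembled, indices are
#' fitted, and the Mann-Kendall test is applied to each index series.
#' These are the empirical series against which simulated trends are
#' compared.
#'
#' @param x a [catch_table()].
#' @param community character vector of species labels.
#' @param region region label.
#' @param measure abundance measure, `"GMA"` or `"LMA"`.
#' @param min_points minimum usable species per year; failing years are
#'   dropped from the series with a warning.
#' @param transform occupancy transform, see [fit_aor()].
#' @return data.frame with one row per index (`tau`, `s_statistic`,
#'   `p_value`, `n_years`); the yearly index series is attached as
#'   attribute `"series"`.
#' @export
empirical_trend <- function(x, community, region,
                            measure = c("GMA", "LMA"), min_points = 3,
                            transform = "asinsqrt") {
  measure <- match.arg(measure)
  years <- sort(unique(x$tow_roster$year[x$tow_roster$region == region]))
  if (length(years) == 0) stop_domain("unknown region: ", region)
  ser <- list()
  for (yr in years) {
    m <- counts_matrix(x, region, yr, species = community)
    fit <- tryCatch(
      fit_aor(aor_points(m, measure), measure = measure,
              min_points = min_points, transform = transform),
      error = function(e) NULL)
    if (is.null(fit)) next
    ser[[length(ser) + 1L]] <-
      data.frame(year = yr, slope = fit$slope, intercept = fit$intercept,
                 r_squared = fit$r_squared, n_points = fit$n_points)
  }
  if (length(ser) < length(years)) {
    warning(length(years) - length(ser),
            " year(s) dropped: too few usable species for the regression",
            call. = FALSE)
  }
  series <- do.call(rbind, ser)
  if (is.null(series) || nrow(series) < 3) {
    stop_domain("fewer than 3 years with a fitted AOR in region ", region)
  }
  rows <- lapply(c("slope", "intercept", "r_squared"), function(idx) {
    mk <- mann_kendall(series[[idx]])
    data.frame(index = idx, tau = mk$tau, s_statistic = mk$s_statistic,
               p_value = mk$p_value, n_years = mk$n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "series") <- series
  attr(out, "measure") <- measure
  out
}
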