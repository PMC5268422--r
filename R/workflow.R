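#' Run a complete AOR trend experiment
#'
#' Chains the full pipeline from a catch table to trend summaries:
#' community selection by the ranked index S, yearly NB fitting with the
#' inclusion filter, Monte-Carlo simulation and survey resampling under
#' the requested experiment, AOR regression per iteration-year,
#' Mann-Kendall trend testing and aggregation, plus the empirical trends
#' computed directly from the catch data. All stage outputs are written
#' to `out_dir` as CSV/JSON and listed in a run manifest.
#'
#' Experiments: `"baseline"` (yearly fitted parameters),
#' `"constant_median"` (each species held at its median parameters), and
#' `"case_study"` (baseline restricted to a year window, run twice: with
#' all species and with `removed_species` deleted, the species-removal
#' contrast).
#'
#' @param catch a [catch_table()] or a path to a catch CSV.
#' @param experiment one of `"baseline"`, `"constant_median"`,
#'   `"case_study"`.
#' @param region region label to analyze.
#' @param out_dir output directory (created if needed).
#' @param n_species community size (default 30).
#' @param years optional year window (required interpretation for
#'   `"case_study"`: defaults to 1973-1982 there).
#' @param removed_species species removed in the case study (default
#'   [gom_aggregating_species]).
#' @param config a [sim_config()]; its `mode` is set from `experiment`.
#' @param roster_path optional roster CSV when `catch` is a path.
#' @param filter inclusion-filter interpretation, see
#'   [fit_yearly_params()].
#' @param allow_fewer passed to [select_community()].
#' @param verbose print stage progress.
#' @return The run manifest (list), invisibly: config snapshot, seed,
#'   package version, per-stage output paths, wall-clock seconds, and
#'   collected warnings.
#' @export
run_experiment <- function(catch,
                           experiment = c("baseline", "constant_median",
                                          "case_study"),
                           region, out_dir, n_species = 30, years = NULL,
                           removed_species = gom_aggregating_species,
                           config = sim_config(), roster_path = NULL,
                           filter = "tows", allow_fewer = TRUE,
                           verbose = TRUE) {
  experiment <- match.arg(experiment)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  say <- function(...) if (verbose) message(...)
  manifest <- list(experiment = experiment, region = region,
                   seed = config$seed,
                   package_version = as.character(
                     utils::packageVersion("aortrend")),
                   config = unclass(config), outputs = list(),
                   timings = list(), warnings = character(0))
  note <- function(w) {
    manifest$warnings <<- c(manifest$warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  stage <- function(name, expr) {
    st <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(
      tryCatch(expr, error = function(e) {
        stop("stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE)
      }),
      warning = note)
    manifest$timings[[name]] <<- round(proc.time()[["elapsed"]] - st, 2)
    res
  }
  out_path <- function(f) file.path(out_dir, f)
  keep <- function(key, path) manifest$outputs[[key]] <<- path

  say("stage: ingest")
  tab <- stage("ingest", {
    if (inherits(catch, "catch_table")) catch
    else read_catch_table(catch, roster_path)
  })

  say("stage: community selection")
  community <- stage("community", {
    select_community(selection_index(tab, region), n = n_species,
                     allow_fewer = allow_fewer)
  })

  say("stage: NB fitting")
  params <- stage("fit_params", {
    sub <- tab
    sub$records <- sub$records[sub$records$region == region, ]
    sub$tow_roster <- sub$tow_roster[sub$tow_roster$region == region, ]
    fit_yearly_params(sub, community, filter = filter)
  })
  write_param_table(params, out_path("params.csv"))
  keep("params", out_path("params.csv"))

  if (experiment == "case_study" && is.null(years)) years <- 1973:1982

  runs <- if (experiment == "case_study") {
    list(all_species = list(mode = "baseline",
                            removed = character(0)),
         removed = list(mode = "species_removal",
                        removed = removed_species))
  } else {
    mode <- if (experiment == "constant_median") "constant_median"
            else "baseline"
    stats::setNames(list(list(mode = mode, removed = character(0))),
                    experiment)
  }

  for (run_name in names(runs)) {
    say("stage: monte carlo [", run_name, "]")
    cfg <- config
    cfg$mode <- runs[[run_name]]$mode
    cfg$removed_species <- runs[[run_name]]$removed
    iters <- stage(paste0("monte_carlo_", run_name), {
      run_monte_carlo(params, region, cfg, years = years)
    })
    f_it <- out_path(paste0("iterations_", run_name, ".csv"))
    utils::write.csv(as.data.frame(iters), f_it, row.names = FALSE,
                     quote = FALSE)
    keep(paste0("iterations_", run_name), f_it)

    say("stage: trends [", run_name, "]")
    tsum <- stage(paste0("trends_", run_name), {
      aggregate_trends(iteration_trends(iters))
    })
    ysum <- stage(paste0("yearly_", run_name), yearly_summary(iters))
    f_ts <- out_path(paste0("trend_summary_", run_name, ".csv"))
    f_tj <- out_path(paste0("trend_summary_", run_name, ".json"))
    f_ys <- out_path(paste0("yearly_summary_", run_name, ".csv"))
    utils::write.csv(as.data.frame(tsum), f_ts, row.names = FALSE,
                     quote = FALSE)
    jsonlite::write_json(tsum, f_tj, dataframe = "rows", digits = NA)
    utils::write.csv(ysum, f_ys, row.names = FALSE, quote = FALSE)
    keep(paste0("trend_summary_", run_name), f_ts)
    keep(paste0("trend_summary_json_", run_name), f_tj)
    keep(paste0("yearly_summary_", run_name), f_ys)
  }

  say("stage: empirical trends")
  emp <- stage("empirical", {
    out <- lapply(config$abundance_measures, function(ms) {
      et <- empirical_trend(tab, community, region, measure = ms,
                            min_points = config$min_points,
                            transform = config$transform)
      if (!is.null(years)) {
        ser <- attr(et, "series")
        ser <- ser[ser$year %in% years, ]
        if (nrow(ser) >= 3) {
          et <- do.call(rbind, lapply(
            c("slope", "intercept", "r_squared"), function(idx) {
              mk <- mann_kendall(ser[[idx]])
              data.frame(index = idx, tau = mk$tau,
                         s_statistic = mk$s_statistic,
                         p_value = mk$p_value, n_years = mk$n)
            }))
        }
      }
      cbind(measure = ms, as.data.frame(et))
    })
    do.call(rbind, out)
  })
  f_emp <- out_path("empirical_trends.csv")
  utils::write.csv(emp, f_emp, row.names = FALSE, quote = FALSE)
  keep("empirical_trends", f_emp)

  manifest$community <- community
  manifest$total_elapsed <- round(proc.time()[["elapsed"]] - t0, 2)
  f_man <- out_path("manifest.json")
  jsonlite::write_json(manifest, f_man, auto_unbox = TRUE, digits = NA,
                       null = "null")
  keep("manifest", f_man)
  say("done in ", manifest$total_elapsed, " s")
  invisible(manifest)
}

#' Plot a yearly summary as line plus confidence ribbon
#'
#' Base-graphics rendering of one index/measure slice of
#' [yearly_summary()]: the across-iteration mean as a solid line with the
#' percentile confidence band as a shaded ribbon, optionally overlaid
#' with the empirical yearly series (dashed).
#'
#' @param ys data.frame from [yearly_summary()].
#' @param index which index to plot.
#' @param measure which abundance measure.
#' @param empirical optional data.frame with columns `year` and the
#'   index (e.g. attribute `"series"` of [empirical_trend()]).
#' @param ... passed to [plot()].
#' @return Invisibly, the plotted subset.
#' @export
plot_yearly_summary <- function(ys, index = "slope", measure = "GMA",
                                empirical = NULL, ...) {
  d <- ys[ys$index == index & ys$measure == measure, ]
  if (nrow(d) == 0) stop_domain("no rows for index ", index, ", measure ",
                                measure)
  d <- d[order(d$year), ]
  ylim <- range(d$ci_low, d$ci_high,
                if (!is.null(empirical)) empirical[[index]])
  plot(d$year, d$mean, type = "n", ylim = ylim, xlab = "year",
       ylab = paste0(index, " (", measure, ")"), ...)
  graphics::polygon(c(d$year, rev(d$year)), c(d$ci_low, rev(d$ci_high)),
                    col = "grey85", border = NA)
  graphics::lines(d$year, d$mean, lwd = 2)
  if (!is.null(empirical)) {
    graphics::lines(empirical$year, empirical[[index]], lty = 2)
  }
  invisible(d)
}
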