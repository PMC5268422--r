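#' Monte-Carlo simulation configuration
#'
#' Bundles the knobs of the community simulation: pool size, survey
#' effort, iteration count, experiment mode and RNG root seed. Defaults
#' follow the study design the package reproduces: 10,000 sites per
#' community, a 55-tow survey, 500 iterations.
#'
#' Modes: `"baseline"` draws each year from that year's fitted
#' parameters; `"constant_median"` holds every species at its
#' across-years median `(mu, k)` for the whole series, nulling out
#' intraspecific temporal variation; `"species_removal"` is the baseline
#' with `removed_species` deleted from every year's community.
#'
#' @param n_sites sites per simulated community (default 10000).
#' @param n_tows tows sampled per year (default 55; must be <= `n_sites`).
#' @param n_iterations Monte-Carlo iterations (default 500).
#' @param mode experiment mode (see Details).
#' @param removed_species species labels to delete in
#'   `"species_removal"` mode.
#' @param seed integer root seed; all randomness derives from it via
#'   [substream_seed()].
#' @param abundance_measures subset of `c("GMA", "LMA")`.
#' @param min_points minimum species for the yearly AOR fit.
#' @param transform occupancy transform, see [fit_aor()].
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_sites = 10000, n_tows = 55, n_iterations = 500,
                       mode = c("baseline", "constant_median",
                                "species_removal"),
                       removed_species = character(0), seed = 1,
                       abundance_measures = c("GMA", "LMA"),
                       min_points = 3, transform = "asinsqrt") {
  mode <- match.arg(mode)
  abundance_measures <- match.arg(abundance_measures, several.ok = TRUE)
  if (n_tows > n_sites) stop_domain("n_tows must not exceed n_sites")
  if (n_iterations < 1) stop_domain("n_iterations must be >= 1")
  structure(list(n_sites = as.integer(n_sites), n_tows = as.integer(n_tows),
                 n_iterations = as.integer(n_iterations), mode = mode,
                 removed_species = as.character(removed_species),
                 seed = as.integer(seed),
                 abundance_measures = abundance_measures,
                 min_points = min_points, transform = transform),
            class = "sim_config")
}

#' Simulate one community-year from NB parameters
#'
#' Draws a species-by-sites count matrix: each row is `n_sites`
#' independent draws from that species' negative binomial `(mu, k)`.
#' Species whose fit hit the `k` boundary (underdispersed samples) are
#' drawn Poisson with mean `mu`, the limiting case; species with status
#' `"not_fit"` are omitted from the matrix. Rows are drawn on independent
#' per-species substreams of `seed` (species sorted by label first), so
#' the matrix is identical for a given seed regardless of input row
#' order.
#'
#' @param year_params data.frame with columns `species`, `mu`, `k`,
#'   `status` (one row per species).
#' @param n_sites number of sites to draw.
#' @param seed stream seed for this community-year.
#' @return Integer matrix, species x sites, rownames = species labels.
#' @export
simulate_community <- function(year_params, n_sites, seed) {
  usable <- year_params[year_params$status %in% c("ok", "boundary_k"), ]
  if (nrow(usable) < 2) {
    stop_domain("fewer than 2 species with usable NB parameters")
  }
  usable <- usable[order(usable$species), ]
  m <- matrix(0L, nrow = nrow(usable), ncol = n_sites,
              dimnames = list(usable$species, NULL))
  for (i in seq_len(nrow(usable))) {
    set.seed(substream_seed(seed, i))
    m[i, ] <- if (usable$status[i] == "boundary_k") {
      stats::rpois(n_sites, usable$mu[i])
    } else {
      stats::rnbinom(n_sites, size = usable$k[i], mu = usable$mu[i])
    }
  }
  m
}

#' Sample a survey from a simulated community
#'
#' Selects `n_tows` site columns uniformly at random without replacement,
#' mimicking a year's trawl survey of the simulated region. All species
#' rows are retained.
#'
#' @param community species x sites matrix from [simulate_community()].
#' @param n_tows number of tows (<= number of sites).
#' @param seed stream seed for the site draw.
#' @return Species x tows matrix with the chosen site indices attached as
#'   attribute `"site_ids"`.
#' @export
sample_survey <- function(community, n_tows, seed) {
  n_sites <- ncol(community)
  if (n_tows > n_sites) {
    stop_domain("n_tows (", n_tows, ") exceeds available sites (",
                n_sites, ")")
  }
  set.seed(substream_seed(seed, 0L))
  idx <- sample.int(n_sites, n_tows)
  out <- community[, idx, drop = FALSE]
  attr(out, "site_ids") <- idx
  out
}

# Assemble the per-year parameter sets a Monte-Carlo run will draw from,
# applying the experiment mode once up front.
year_param_sets <- function(params, region, config) {
  p <- params[params$region == region, ]
  if (nrow(p) == 0) stop_domain("unknown region: ", region)
  years <- sort(unique(p$year))
  if (length(years) < 3) stop_domain("need at least 3 years for region ",
                                     region)
  if (config$mode == "constant_median") {
    med <- median_params(p)
    sets <- lapply(years, function(yr) med[c("species", "mu", "k", "status")])
  } else {
    sets <- lapply(years, function(yr) {
      p[p$year == yr, c("species", "mu", "k", "status")]
    })
    if (config$mode == "species_removal") {
      present <- unique(p$species)
      unknown <- setdiff(config$removed_species, present)
      if (length(unknown) > 0) {
        warning("removed_species not in community, ignored: ",
                paste(unknown, collapse = ", "), call. = FALSE)
      }
      sets <- lapply(sets, function(s) {
        s[!s$species %in% config$removed_species, ]
      })
    }
  }
  names(sets) <- years
  sets
}

#' Run the Monte-Carlo AOR experiment
#'
#' The simulation core: for every iteration and every year of the region,
#' generates a community from the year's NB parameter set (according to
#' the experiment mode), samples a survey of `n_tows` sites, and fits the
#' AOR regression for each requested abundance measure. Per-(iteration,
#' year, species) RNG substreams are derived from the root seed, so runs
#' are bitwise reproducible and any slice can be regenerated in
#' isolation.
#'
#' Years with too few usable species for the community or the regression
#' yield NA indices for that iteration-year (counted in a warning).
#'
#' @param params a `param_table` from [fit_yearly_params()] (or any
#'   data.frame with columns `region`, `year`, `species`, `mu`, `k`,
#'   `status`).
#' @param region region label to simulate.
#' @param config a [sim_config()].
#' @param years optional integer vector restricting the simulated years
#'   (e.g. a case-study window); default all fitted years of the region.
#' @return data.frame of class `aor_iterations`: columns `iteration`,
#'   `year`, `measure`, `slope`, `intercept`, `r_squared`, `n_points`,
#'   with `region` and the config stored in attributes.
#' @export
run_monte_carlo <- function(params, region, config = sim_config(),
                            years = NULL) {
  stopifnot(inherits(config, "sim_config"))
  sets <- year_param_sets(params, region, config)
  yrs <- as.integer(names(sets))
  if (!is.null(years)) {
    keep <- yrs %in% years
    if (sum(keep) < 3) stop_domain("fewer than 3 requested years available")
    sets <- sets[keep]
    yrs <- yrs[keep]
  }
  n_yr <- length(yrs)
  n_it <- config$n_iterations
  measures <- config$abundance_measures
  n_failed <- 0L

  out <- vector("list", n_it)
  for (it in seq_len(n_it)) {
    rows <- vector("list", n_yr * length(measures))
    ri <- 0L
    for (j in seq_len(n_yr)) {
      stream <- substream_seed(config$seed, it, j)
      res <- tryCatch({
        comm <- simulate_community(sets[[j]], config$n_sites, stream)
        sample_survey(comm, config$n_tows, substream_seed(stream, 999983L))
      }, error = function(e) NULL)
      for (ms in measures) {
        fit <- NULL
        if (!is.null(res)) {
          fit <- tryCatch(
            fit_aor(aor_points(res, ms), measure = ms,
                    min_points = config$min_points,
                    transform = config$transform),
            error = function(e) NULL)
        }
        if (is.null(fit)) n_failed <- n_failed + 1L
        ri <- ri + 1L
        rows[[ri]] <- data.frame(
          iteration = it, year = yrs[j], measure = ms,
          slope = if (is.null(fit)) NA_real_ else fit$slope,
          intercept = if (is.null(fit)) NA_real_ else fit$intercept,
          r_squared = if (is.null(fit)) NA_real_ else fit$r_squared,
          n_points = if (is.null(fit)) NA_integer_ else fit$n_points,
          stringsAsFactors = FALSE)
      }
    }
    out[[it]] <- do.call(rbind, rows)
  }
  if (n_failed > 0) {
    warning(n_failed, " iteration-year cells could not be fitted (NA)",
            call. = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "region") <- region
  attr(res, "config") <- config
  class(res) <- c("aor_iterations", "data.frame")
  res
}

#' The seven schooling/aggregating Gulf of Maine species
#'
#' Species identified as schooling or occurring in dense aggregations,
#' whose rise in relative abundance during 1973-1982 the removal case
#' study examines: alewife, American shad, Atlantic argentine, Atlantic
#' herring, longfin squid, northern shortfin squid, and sea scallop.
#'
#' @format Character vector of seven scientific names.
#' @export
gom_aggregating_species <- c(
  "Alosa pseudoharengus", "Alosa sapidissima", "Argentina silus",
  "Clupea harengus", "Doryteuthis pealeii", "Illex illecebrosus",
  "Placopecten magellanicus")
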