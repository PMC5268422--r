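#' Negative binomial probability mass function (mu, k parameterization)
#'
#' Evaluates `p(x) = C(x + k - 1, x) * (k/(k+mu))^k * (mu/(k+mu))^x`, the
#' negative binomial pmf with mean `mu` and aggregation (size) parameter
#' `k`. Smaller `k` means a patchier spatial distribution: the variance is
#' `mu + mu^2/k`, and the probability of an empty tow, `(k/(k+mu))^k`,
#' increases as `k` falls with `mu` fixed.
#'
#' Computed on the log scale via `lgamma` for numerical stability.
#'
#' @param x non-negative integer count(s).
#' @param mu mean count per tow (> 0).
#' @param k aggregation parameter (> 0).
#' @return Probability in `[0, 1]`, vectorized over `x`.
#' @export
nb_pmf <- function(x, mu, k) {
  if (!is.numeric(mu) || any(mu <= 0)) stop_domain("mu must be > 0")
  if (!is.numeric(k) || any(k <= 0)) stop_domain("k must be > 0")
  if (any(x < 0 | x != floor(x))) {
    stop_domain("x must be a non-negative integer")
  }
  exp(lgamma(x + k) - lgamma(k) - lgamma(x + 1) +
        k * log(k / (k + mu)) + x * log(mu / (k + mu)))
}

#' Probability parameter p from (mu, k)
#'
#' `p = k / (k + mu)`, the success-probability parameterization of the
#' negative binomial. Equals 1 when `mu = 0` and decreases towards 0 as
#' the mean grows relative to `k`.
#'
#' @param mu mean count per tow (>= 0).
#' @param k aggregation parameter (> 0).
#' @return Value in `(0, 1]`.
#' @export
p_from_mu_k <- function(mu, k) {
  if (!is.numeric(k) || any(k <= 0)) stop_domain("k must be > 0")
  if (!is.numeric(mu) || any(mu < 0)) stop_domain("mu must be >= 0")
  k / (k + mu)
}

# Profile log-likelihood in k; the NB MLE of mu is the sample mean for
# any k, so the 2-d maximization reduces to one dimension.
nb_profile_loglik <- function(k, counts, mu) {
  n <- length(counts)
  sum(lgamma(counts + k)) - n * lgamma(k) - sum(lgamma(counts + 1)) +
    n * k * log(k / (k + mu)) + sum(counts) * log(mu / (k + mu))
}

#' Fit a negative binomial distribution to per-tow counts
#'
#' Maximum-likelihood fit of `(mu, k)` to a vector of counts, intended for
#' one species' catches over all tows of a region-year (zeros included).
#' The mean is estimated analytically (`mu_hat` = sample mean, an exact
#' property of the NB MLE) and `k` by numerical maximization of the
#' profile log-likelihood.
#'
#' Underdispersed samples (variance <= mean) have no interior NB maximum:
#' the likelihood increases without bound in `k`, approaching a Poisson.
#' Such fits are capped at `k_cap` and flagged `status = "boundary_k"`;
#' downstream simulation treats them as Poisson with mean `mu`. Samples
#' with fewer than 3 counts, or with no positive count, are flagged
#' `"not_fit"`.
#'
#' @param counts integer vector of non-negative per-tow counts.
#' @param k_cap upper cap for `k` (default `1e4`).
#' @return Object of class `nb_params`: list with `mu`, `k`, `status`
#'   (one of `"ok"`, `"boundary_k"`, `"not_fit"`), `n_tows`, `n_occupied`,
#'   and `loglik` (NA when not fitted).
#' @export
fit_nb <- function(counts, k_cap = 1e4) {
  if (any(counts < 0 | counts != floor(counts))) {
    stop_domain("counts must be non-negative integers")
  }
  n <- length(counts)
  occ <- sum(counts > 0)
  out <- list(mu = NA_real_, k = NA_real_, status = "not_fit",
              n_tows = n, n_occupied = occ, loglik = NA_real_)
  class(out) <- "nb_params"
  if (n < 3 || occ == 0) {
    return(out)
  }
  m <- mean(counts)
  v <- stats::var(counts)
  out$mu <- m
  if (v <= m) {
    out$k <- k_cap
    out$status <- "boundary_k"
    out$loglik <- nb_profile_loglik(k_cap, counts, m)
    return(out)
  }
  # maximize over log k for scale robustness
  obj <- function(lk) nb_profile_loglik(exp(lk), counts, m)
  opt <- stats::optimize(obj, interval = c(log(1e-4), log(k_cap)),
                         maximum = TRUE, tol = 1e-8)
  k_hat <- exp(opt$maximum)
  if (k_hat >= 0.99 * k_cap) {
    out$k <- k_cap
    out$status <- "boundary_k"
    out$loglik <- nb_profile_loglik(k_cap, counts, m)
  } else {
    out$k <- k_hat
    out$status <- "ok"
    out$loglik <- opt$objective
  }
  out
}

#' @export
print.nb_params <- function(x, ...) {
  cat(sprintf("nb_params: mu = %.4g, k = %.4g [%s], %d tows (%d occupied)\n",
              x$mu, x$k, x$status, x$n_tows, x$n_occupied))
  invisible(x)
}

#' Fit yearly NB parameters for a community
#'
#' For every (region, year, species) combination, assembles the count
#' vector over the full tow roster (zeros included) and fits a negative
#' binomial, subject to the inclusion filter: a species enters a year only
#' if it was caught more than twice. Two readings of that rule are
#' supported: present in at least 3 tows of the region-year (`"tows"`, the
#' default) or at least 3 total individuals (`"individuals"`).
#' Species-years failing the filter are retained with `status = "not_fit"`
#' and NA parameters so the bookkeeping stays explicit.
#'
#' @param x a [catch_table()].
#' @param community character vector of species labels (see
#'   [select_community()]).
#' @param filter inclusion-filter interpretation, `"tows"` or
#'   `"individuals"`.
#' @param k_cap upper cap on `k`, passed to [fit_nb()].
#' @return A `param_table`: data.frame with columns `region`, `year`,
#'   `species`, `mu`, `k`, `status`, `n_tows`, `n_occupied`, with the
#'   filter rule recorded in attributes.
#' @export
fit_yearly_params <- function(x, community, filter = c("tows", "individuals"),
                              k_cap = 1e4) {
  stopifnot(inherits(x, "catch_table"))
  filter <- match.arg(filter)
  extra <- setdiff(community, unique(x$records$species))
  if (length(extra) > 0) {
    stop_domain("community species not present in table: ",
                paste(extra, collapse = ", "))
  }
  ry <- unique(x$tow_roster[c("region", "year")])
  ry <- ry[order(ry$region, ry$year), ]
  rows <- vector("list", nrow(ry) * length(community))
  ri <- 0L
  for (i in seq_len(nrow(ry))) {
    m <- counts_matrix(x, ry$region[i], ry$year[i], species = community)
    for (sp in community) {
      cnt <- m[sp, ]
      pass <- if (filter == "tows") sum(cnt > 0) >= 3 else sum(cnt) >= 3
      fit <- if (pass) {
        fit_nb(cnt, k_cap = k_cap)
      } else {
        list(mu = NA_real_, k = NA_real_, status = "not_fit",
             n_tows = length(cnt), n_occupied = sum(cnt > 0))
      }
      ri <- ri + 1L
      rows[[ri]] <- data.frame(region = ry$region[i], year = ry$year[i],
                               species = sp, mu = fit$mu, k = fit$k,
                               status = fit$status, n_tows = fit$n_tows,
                               n_occupied = fit$n_occupied,
                               stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows[seq_len(ri)])
  rownames(out) <- NULL
  attr(out, "filter") <- filter
  attr(out, "k_cap") <- k_cap
  class(out) <- c("param_table", "data.frame")
  out
}

#' Median NB parameters per species
#'
#' Collapses a parameter table to one `(mu, k)` pair per (region, species):
#' the medians, taken independently per parameter, over the years with
#' `status = "ok"`. Even year counts use the midpoint convention of
#' [stats::median()]. These constants drive the constant-parameter null
#' experiment, which removes intraspecific temporal variation while
#' preserving the interspecific mix of spatial behaviors.
#'
#' @param params a `param_table` from [fit_yearly_params()].
#' @return data.frame with columns `region`, `species`, `mu`, `k`,
#'   `status` (always `"ok"`), `n_years` (ok-status years used). Species
#'   with no ok-status year are excluded with a warning.
#' @export
median_params <- function(params) {
  ok <- params[params$status == "ok", ]
  all_sp <- unique(params[c("region", "species")])
  if (nrow(ok) == 0) stop_domain("no species has a fitted (status ok) year")
  key <- paste(ok$region, ok$species, sep = "\r")
  mu <- tapply(ok$mu, key, stats::median)
  k <- tapply(ok$k, key, stats::median)
  ny <- tapply(ok$mu, key, length)
  parts <- strsplit(names(mu), "\r", fixed = TRUE)
  out <- data.frame(region = vapply(parts, `[`, "", 1),
                    species = vapply(parts, `[`, "", 2),
                    mu = as.numeric(mu), k = as.numeric(k),
                    status = "ok", n_years = as.integer(ny),
                    stringsAsFactors = FALSE)
  dropped <- nrow(all_sp) - nrow(out)
  if (dropped > 0) {
    warning(dropped, " species with no ok-status year excluded from medians",
            call. = FALSE)
  }
  out <- out[order(out$region, out$species), ]
  rownames(out) <- NULL
  out
}

#' Temporal trend in a community-mean NB parameter
#'
#' Builds the yearly cross-species arithmetic mean of a fitted NB
#' parameter for one region and applies the Mann-Kendall trend test to the
#' year series. For `mu` the mean is taken over species with status `ok`
#' or `boundary_k` (the mean estimate is valid at the boundary); for `k`
#' only `ok` fits enter, since the boundary cap is a censoring value, not
#' an estimate. Species not fitted in a year are simply absent from that
#' year's mean.
#'
#' @param params a `param_table` from [fit_yearly_params()].
#' @param region region label.
#' @param parameter `"mu"` or `"k"`.
#' @return Object of class `param_trend`: list with `region`, `parameter`,
#'   `tau`, `p_value`, and `series` (data.frame year, value, n_species).
#' @export
parameter_trend <- function(params, region, parameter = c("mu", "k")) {
  parameter <- match.arg(parameter)
  p <- params[params$region == region, ]
  if (nrow(p) == 0) stop_domain("unknown region: ", region)
  keep <- if (parameter == "mu") p$status %in% c("ok", "boundary_k")
          else p$status == "ok"
  p <- p[keep, ]
  val <- tapply(p[[parameter]], p$year, mean)
  series <- data.frame(year = as.integer(names(val)),
                       value = as.numeric(val),
                       n_species = as.integer(tapply(p$year, p$year, length)))
  series <- series[order(series$year), ]
  rownames(series) <- NULL
  if (nrow(series) < 3) {
    stop_domain("fewer than 3 usable years for ", parameter,
                " in region ", region)
  }
  mk <- mann_kendall(series$value)
  structure(list(region = region, parameter = parameter,
                 tau = mk$tau, p_value = mk$p_value, series = series),
            class = "param_trend")
}

#' @export
print.param_trend <- function(x, ...) {
  cat(sprintf("trend in mean %s, region %s: tau = %.3f (p = %.3g), %d years\n",
              x$parameter, x$region, x$tau, x$p_value, nrow(x$series)))
  invisible(x)
}

#' Write / read a parameter table
#'
#' CSV round-trip for [fit_yearly_params()] output (columns `region`,
#' `year`, `species`, `mu`, `k`, `status`, `n_tows`, `n_occupied`).
#'
#' @param params a `param_table`.
#' @param path CSV path.
#' @return `write_param_table` returns `params` invisibly;
#'   `read_param_table` returns a `param_table`.
#' @export
write_param_table <- function(params, path) {
  utils::write.csv(as.data.frame(params), path, row.names = FALSE,
                   quote = FALSE)
  invisible(params)
}

#' @rdname write_param_table
#' @export
read_param_table <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("region", "year", "species", "mu", "k", "status")
  miss <- setdiff(req, names(out))
  if (length(miss) > 0) {
    stop_domain("parameter table missing column(s): ",
                paste(miss, collapse = ", "))
  }
  class(out) <- c("param_table", "data.frame")
  out
}
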