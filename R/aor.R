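#' Occupancy per species
#'
#' The proportion of sampled tows in which each species is present (count
#' >= 1). Rows of the sample matrix are species, columns are tows.
#'
#' @param sample species x tows count matrix.
#' @return Named numeric vector of occupancies in `[0, 1]`.
#' @export
occupancy <- function(sample) {
  sample <- as.matrix(sample)
  if (ncol(sample) < 1) stop_domain("sample has no tows")
  rowMeans(sample > 0)
}

#' Mean abundance per species (GMA or LMA)
#'
#' Global mean abundance (GMA) is total catch divided by the total number
#' of tows; local mean abundance (LMA) divides by occupied tows only, so
#' it measures density where the species actually occurs. The two are
#' linked through occupancy: `GMA = LMA * O` exactly. LMA is undefined
#' (NA) for species caught in no tow.
#'
#' @param sample species x tows count matrix.
#' @param measure `"GMA"` or `"LMA"`.
#' @return Named numeric vector (individuals per tow).
#' @export
abundance <- function(sample, measure = c("GMA", "LMA")) {
  measure <- match.arg(measure)
  sample <- as.matrix(sample)
  if (ncol(sample) < 1) stop_domain("sample has no tows")
  tot <- rowSums(sample)
  if (measure == "GMA") {
    tot / ncol(sample)
  } else {
    occ <- rowSums(sample > 0)
    ifelse(occ > 0, tot / occ, NA_real_)
  }
}

#' Abundance-occupancy points for one sampled community-year
#'
#' @param sample species x tows count matrix.
#' @param measure abundance measure, `"GMA"` or `"LMA"`.
#' @return data.frame with columns `species`, `O` (occupancy), `A`
#'   (abundance), one row per species row of `sample`.
#' @export
aor_points <- function(sample, measure = c("GMA", "LMA")) {
  measure <- match.arg(measure)
  sample <- as.matrix(sample)
  sp <- rownames(sample) %||% paste0("sp", seq_len(nrow(sample)))
  data.frame(species = sp,
             O = unname(occupancy(sample)),
             A = unname(abundance(sample, measure)),
             stringsAsFactors = FALSE)
}

#' Fit the interspecific abundance-occupancy regression
#'
#' Ordinary least squares of transformed occupancy on log abundance,
#' `asin(sqrt(O)) ~ ln(A)`, across the species of one community-year. The
#' slope, intercept and R-squared serve as indices of community state: the
#' slope measures how unequally occupied habitat is spread across
#' abundance levels, the intercept sets community-wide habitat occupation,
#' and R-squared indexes the homogeneity of spatial strategies.
#'
#' Species with zero sampled catch are excluded (log abundance undefined);
#' `n_points` records how many species entered the fit. The
#' arcsine-square-root transform is the standard variance-stabilizer for
#' proportions and maps `O = 1` to `pi/2` exactly, so no clamping is
#' needed; a plain `asin(O)` variant is available via `transform`.
#'
#' @param points data.frame from [aor_points()] (columns `O`, `A`).
#' @param measure optional abundance-measure label carried through to the
#'   result.
#' @param min_points minimum species required (default 3: a line plus one
#'   residual degree of freedom).
#' @param transform `"asinsqrt"` (default) or `"asin"`.
#' @return Object of class `aor_fit`: list with `slope`, `intercept`,
#'   `r_squared`, `n_points`, `measure`, `transform`.
#' @export
fit_aor <- function(points, measure = NULL, min_points = 3,
                    transform = c("asinsqrt", "asin")) {
  transform <- match.arg(transform)
  usable <- !is.na(points$A) & points$A > 0 & points$O > 0
  pts <- points[usable, ]
  if (nrow(pts) < min_points) {
    stop_domain("only ", nrow(pts), " usable species (need ", min_points,
                ") for the AOR regression")
  }
  x <- log(pts$A)
  y <- if (transform == "asinsqrt") asin(sqrt(pts$O)) else asin(pts$O)
  if (stats::var(y) == 0 || stats::var(x) == 0) {
    # degenerate: no occupancy (or abundance) variation; slope indexes
    # nothing and the line explains nothing
    fit <- list(slope = 0, intercept = mean(y), r_squared = 0)
  } else {
    mod <- stats::lm(y ~ x)
    r2 <- 1 - sum(stats::residuals(mod)^2) / sum((y - mean(y))^2)
    fit <- list(slope = unname(stats::coef(mod)[2]),
                intercept = unname(stats::coef(mod)[1]),
                r_squared = min(max(r2, 0), 1))
  }
  structure(c(fit, list(n_points = nrow(pts), measure = measure,
                        transform = transform)),
            class = "aor_fit")
}

#' @export
print.aor_fit <- function(x, ...) {
  cat(sprintf(
    "aor_fit (%s): slope = %.4f, intercept = %.4f, R2 = %.3f, n = %d\n",
    x$measure %||% "?", x$slope, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}
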