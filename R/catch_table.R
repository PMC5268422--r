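#' Construct a catch table
#'
#' A catch table is the package's container for tow-level survey catches:
#' a long-format record set (region, year, tow, species, count) plus a tow
#' roster listing every tow made in each region-year, including tows that
#' caught none of the recorded species. The roster is what makes occupancy
#' denominators and zero counts recoverable: a species' count vector for a
#' region-year always spans the full roster, with zeros filled in.
#'
#' Duplicate (region, year, tow, species) rows are summed on construction;
#' raw survey exports often split a haul's catch of one species across rows
#' (for example by length class or sex). Zero-count rows are dropped from
#' the records after their tows have been added to the roster.
#'
#' @param records data.frame with columns `region`, `year`, `tow`,
#'   `species`, `count` (non-negative integers).
#' @param tow_roster optional data.frame with columns `region`, `year`,
#'   `tow`; must contain every tow appearing in `records`. When `NULL` the
#'   roster is inferred as the distinct tows observed in `records`, which
#'   understates effort only if some tow caught none of the ingested
#'   species.
#' @return An object of class `catch_table`: a list with elements
#'   `records` and `tow_roster`.
#' @seealso [read_catch_table()], [selection_index()]
#' @export
catch_table <- function(records, tow_roster = NULL) {
  req <- c("region", "year", "tow", "species", "count")
  miss <- setdiff(req, names(records))
  if (length(miss) > 0) {
    stop_domain("records is missing required column(s): ",
                paste(miss, collapse = ", "))
  }
  records <- as.data.frame(records)[req]
  records$region <- as.character(records$region)
  records$tow <- as.character(records$tow)
  records$species <- as.character(records$species)

  cnt <- records$count
  bad <- which(is.na(cnt) | cnt < 0 | cnt != floor(cnt))
  if (length(bad) > 0) {
    stop_domain("count must be a non-negative integer; offending row(s): ",
                paste(utils::head(bad, 5), collapse = ", "))
  }
  if (any(is.na(records$year) | records$year != floor(records$year))) {
    stop_domain("year must be an integer")
  }
  records$year <- as.integer(records$year)
  records$count <- as.integer(records$count)

  observed <- unique(records[c("region", "year", "tow")])
  if (is.null(tow_roster)) {
    tow_roster <- observed
  } else {
    tow_roster <- as.data.frame(tow_roster)[c("region", "year", "tow")]
    tow_roster$region <- as.character(tow_roster$region)
    tow_roster$year <- as.integer(tow_roster$year)
    tow_roster$tow <- as.character(tow_roster$tow)
    tow_roster <- unique(tow_roster)
    key_obs <- do.call(paste, c(observed, sep = "\r"))
    key_ros <- do.call(paste, c(tow_roster, sep = "\r"))
    if (!all(key_obs %in% key_ros)) {
      stop_domain("tow_roster does not cover all tows present in records")
    }
  }
  tow_roster <- tow_roster[order(tow_roster$region, tow_roster$year,
                                 tow_roster$tow), ]
  rownames(tow_roster) <- NULL

  # sum duplicates, then drop zero-count rows (their tows are in the roster)
  if (nrow(records) > 0) {
    records <- stats::aggregate(count ~ region + year + tow + species,
                                data = records, FUN = sum)
    records$count <- as.integer(records$count)
    records <- records[records$count > 0, ]
    records <- records[order(records$region, records$year, records$tow,
                             records$species), ]
    rownames(records) <- NULL
  }

  structure(list(records = records, tow_roster = tow_roster),
            class = "catch_table")
}

#' @export
print.catch_table <- function(x, ...) {
  nreg <- length(unique(x$tow_roster$region))
  yrs <- range(x$tow_roster$year)
  cat("catch_table:", nrow(x$records), "records,",
      length(unique(x$records$species)), "species,",
      nreg, "region(s), years", yrs[1], "-", yrs[2], "\n")
  cat("  tow roster:", nrow(x$tow_roster), "tows\n")
  invisible(x)
}

#' Read a catch table from CSV
#'
#' Reads a long-format catch CSV (header columns `region`, `year`, `tow`,
#' `species`, `count`) and, optionally, a tow-roster CSV. The roster file
#' may either list tows explicitly (columns `region`, `year`, `tow`) or
#' give per-year effort (columns `region`, `year`, `n_tows`), in which case
#' unobserved tows are padded with synthetic identifiers so that zero
#' catches are representable. Supplying a roster is recommended whenever
#' tows may have caught none of the ingested species.
#'
#' @param path path to the catch CSV.
#' @param roster_path optional path to the roster CSV.
#' @return A [catch_table()].
#' @export
read_catch_table <- function(path, roster_path = NULL) {
  records <- utils::read.csv(path, stringsAsFactors = FALSE)
  roster <- NULL
  if (!is.null(roster_path)) {
    rf <- utils::read.csv(roster_path, stringsAsFactors = FALSE)
    if (all(c("region", "year", "tow") %in% names(rf))) {
      roster <- rf[c("region", "year", "tow")]
    } else if (all(c("region", "year", "n_tows") %in% names(rf))) {
      roster <- expand_roster_counts(rf, records)
    } else {
      stop_domain("roster file must have columns region, year, tow ",
                  "or region, year, n_tows")
    }
  }
  catch_table(records, roster)
}

# Turn a (region, year, n_tows) effort table into an explicit tow list:
# observed tow ids first, then synthetic "pad" ids up to n_tows.
expand_roster_counts <- function(effort, records) {
  out <- vector("list", nrow(effort))
  for (i in seq_len(nrow(effort))) {
    reg <- as.character(effort$region[i])
    yr <- as.integer(effort$year[i])
    n <- as.integer(effort$n_tows[i])
    obs <- sort(unique(as.character(
      records$tow[records$region == reg & records$year == yr])))
    if (length(obs) > n) {
      stop_domain("roster n_tows (", n, ") for ", reg, " ", yr,
                  " is smaller than the ", length(obs), " observed tows")
    }
    pad <- if (n > length(obs)) sprintf("pad%04d", seq_len(n - length(obs)))
           else character(0)
    out[[i]] <- data.frame(region = reg, year = yr, tow = c(obs, pad),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Write a catch table to CSV
#'
#' Inverse of [read_catch_table()]: writes the records as a catch CSV and,
#' optionally, the tow roster as an explicit tow-list CSV.
#'
#' @param x a [catch_table()].
#' @param path output path for the catch CSV.
#' @param roster_path optional output path for the roster CSV.
#' @return `x`, invisibly.
#' @export
write_catch_table <- function(x, path, roster_path = NULL) {
  stopifnot(inherits(x, "catch_table"))
  utils::write.csv(x$records, path, row.names = FALSE, quote = FALSE)
  if (!is.null(roster_path)) {
    utils::write.csv(x$tow_roster, roster_path, row.names = FALSE,
                     quote = FALSE)
  }
  invisible(x)
}

#' Species-selection index S
#'
#' Ranks the species ever caught in a region by
#' `S = H_i / H_max + y_i / y_tot`, where `H_i` is species i's total catch
#' over all survey years, `H_max` the regional maximum of those totals,
#' `y_i` the number of surveyed years in which the species was caught, and
#' `y_tot` the total number of surveyed years in the region (taken from the
#' tow roster). S lies in (0, 2] and favours species that are both abundant
#' and consistently present, screening out rare species whose occupancy is
#' poorly estimated by the survey.
#'
#' @param x a [catch_table()].
#' @param region region label present in `x`.
#' @return data.frame with columns `species`, `H_i`, `H_max`, `y_i`,
#'   `y_tot`, `S`, sorted by decreasing S (ties broken by species label).
#' @export
selection_index <- function(x, region) {
  stopifnot(inherits(x, "catch_table"))
  if (!region %in% x$tow_roster$region) {
    stop_domain("unknown region: ", region)
  }
  rec <- x$records[x$records$region == region, ]
  if (nrow(rec) == 0) {
    stop_domain("no catches recorded in region ", region)
  }
  y_tot <- length(unique(x$tow_roster$year[x$tow_roster$region == region]))
  h <- tapply(rec$count, rec$species, sum)
  yrs <- tapply(rec$year, rec$species, function(v) length(unique(v)))
  sp <- names(h)
  out <- data.frame(species = sp,
                    H_i = as.numeric(h),
                    H_max = max(as.numeric(h)),
                    y_i = as.integer(yrs[sp]),
                    y_tot = y_tot,
                    stringsAsFactors = FALSE)
  out$S <- out$H_i / out$H_max + out$y_i / out$y_tot
  out <- out[order(-out$S, out$species), ]
  rownames(out) <- NULL
  out
}

#' Select the community for a region
#'
#' Takes the top `n` species from a [selection_index()] ranking. The same
#' species set is used for every year of the region, so that AOR indices
#' track a consistent assemblage. Ties in S are broken by species label
#' (ascending), making the selection deterministic.
#'
#' @param scores data.frame from [selection_index()].
#' @param n community size (default 30 species).
#' @param allow_fewer if `TRUE`, return all species (with a warning) when
#'   fewer than `n` are available; otherwise error.
#' @return Character vector of species labels.
#' @export
select_community <- function(scores, n = 30, allow_fewer = FALSE) {
  stopifnot(is.data.frame(scores), all(c("species", "S") %in% names(scores)))
  if (n < 2) stop_domain("community size n must be at least 2")
  scores <- scores[order(-scores$S, scores$species), ]
  if (nrow(scores) < n) {
    if (!allow_fewer) {
      stop_domain("only ", nrow(scores), " species available, n = ", n,
                  " requested (set allow_fewer = TRUE to accept)")
    }
    warning("only ", nrow(scores), " species available; using all of them",
            call. = FALSE)
    n <- nrow(scores)
  }
  scores$species[seq_len(n)]
}

#' Per-tow count matrix for one region-year
#'
#' Assembles the species-by-tow count matrix for a region-year over the
#' full tow roster: tows in which a species was not caught contribute
#' explicit zeros. This matrix is the unit on which distributions are
#' fitted and occupancy is measured.
#'
#' @param x a [catch_table()].
#' @param region region label.
#' @param year integer year.
#' @param species character vector of species rows to include (default:
#'   all species caught in the region, sorted).
#' @return Integer matrix, species x tows, with dimnames.
#' @export
counts_matrix <- function(x, region, year, species = NULL) {
  stopifnot(inherits(x, "catch_table"))
  tows <- x$tow_roster$tow[x$tow_roster$region == region &
                           x$tow_roster$year == year]
  if (length(tows) == 0) {
    stop_domain("no tows in roster for region ", region, ", year ", year)
  }
  tows <- sort(tows)
  if (is.null(species)) {
    species <- sort(unique(x$records$species[x$records$region == region]))
  }
  m <- matrix(0L, nrow = length(species), ncol = length(tows),
              dimnames = list(species, tows))
  rec <- x$records[x$records$region == region & x$records$year == year &
                   x$records$species %in% species, ]
  if (nrow(rec) > 0) {
    m[cbind(match(rec$species, species), match(rec$tow, tows))] <-
      rec$count
  }
  m
}
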