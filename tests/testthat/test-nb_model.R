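test_that("nb_pmf matches the gamma-function form and normalizes", {
  expect_equal(nb_pmf(0, mu = 1, k = 1), 0.5)
  expect_lt(abs(sum(nb_pmf(0:500, mu = 3, k = 0.7)) - 1), 1e-9)

  # independent oracle: the same pmf through stats::dnbinom
  grid <- expand.grid(x = 0:20, mu = c(0.3, 2, 9), k = c(0.2, 1, 5))
  expect_equal(nb_pmf(grid$x, grid$mu, grid$k),
               dnbinom(grid$x, size = grid$k, mu = grid$mu),
               tolerance = 1e-12)

  expect_error(nb_pmf(2, mu = 0, k = 1), "mu")
  expect_error(nb_pmf(2, mu = 1, k = -1), "k")
  expect_error(nb_pmf(1.5, mu = 1, k = 1), "integer")
})

test_that("p_from_mu_k follows k/(k + mu)", {
  expect_equal(p_from_mu_k(3, 3), 0.5)
  expect_equal(p_from_mu_k(0, 2), 1)
  expect_equal(p_from_mu_k(3, 1), 0.25)
  expect_error(p_from_mu_k(1, 0), "k")
})

test_that("lower k at fixed mu concentrates mass at zero (aggregation)", {
  ks <- c(10, 5, 1, 0.5, 0.2, 0.05)
  p0 <- nb_pmf(0, mu = 2, k = ks)
  expect_true(all(diff(p0) > 0))
})

test_that("fit_nb handles degenerate samples via status flags", {
  # underdispersed: no interior MLE, k capped
  fit <- fit_nb(rep(4L, 20))
  expect_equal(fit$status, "boundary_k")
  expect_equal(fit$mu, 4)
  expect_equal(fit$k, 1e4)

  expect_equal(fit_nb(rep(0L, 10))$status, "not_fit")
  expect_equal(fit_nb(c(1L, 2L))$status, "not_fit")
  expect_error(fit_nb(c(-1, 2, 3)), "non-negative")
})

test_that("fit_nb recovers known parameters from large samples", {
  set.seed(401)
  x <- rnbinom(10000, size = 0.5, mu = 5)
  fit <- fit_nb(x)
  expect_equal(fit$status, "ok")
  expect_gt(fit$mu, 4.7); expect_lt(fit$mu, 5.3)
  expect_gt(fit$k, 0.45); expect_lt(fit$k, 0.55)
  expect_equal(fit$mu, mean(x))  # NB MLE property: mu-hat is the sample mean

  # sample variance approaches mu + mu^2/k
  set.seed(402)
  y <- rnbinom(1e5, size = 1, mu = 5)
  expect_lt(abs(var(y) - 30) / 30, 0.05)
})

test_that("fit_nb beats a brute-force likelihood grid on small samples", {
  loglik <- function(counts, mu, k) {
    sum(lgamma(counts + k) - lgamma(k) - lgamma(counts + 1) +
          k * log(k / (k + mu)) + counts * log(mu / (k + mu)))
  }
  for (seed in c(11, 12, 13)) {
    set.seed(seed)
    x <- rnbinom(20, size = 0.8, mu = 3)
    if (sum(x > 0) == 0 || var(x) <= mean(x)) next
    fit <- fit_nb(x)
    mus <- seq(0.05, 3 * mean(x), length.out = 60)
    ks <- exp(seq(log(0.01), log(50), length.out = 80))
    grid_best <- max(outer(mus, ks, Vectorize(function(m, kk)
      loglik(x, m, kk))))
    expect_gte(fit$loglik, grid_best - 1e-6)
  }
})

test_that("fit_nb agrees with the classical ML fit", {
  skip_if_not_installed("MASS")
  set.seed(77)
  x <- rnbinom(400, size = 1.3, mu = 4)
  fit <- fit_nb(x)
  ref <- MASS::fitdistr(x, "negative binomial")
  expect_equal(fit$k, unname(ref$estimate["size"]), tolerance = 1e-3)
  expect_equal(fit$mu, unname(ref$estimate["mu"]), tolerance = 1e-3)
})

test_that("fit_yearly_params applies the caught-more-than-twice filter", {
  # one year, 6 tows; sparse caught in 2 tows, border in 3, common in 5
  records <- data.frame(
    region = "R", year = 1990,
    tow = c("t1", "t2", "t1", "t2", "t3", "t1", "t2", "t3", "t4", "t5"),
    species = c("sparse", "sparse", rep("border", 3), rep("common", 5)),
    count = c(5, 2, 1, 1, 1, 2, 3, 1, 4, 2))
  roster <- data.frame(region = "R", year = 1990,
                       tow = paste0("t", 1:6))
  tab <- catch_table(records, roster)
  p <- fit_yearly_params(tab, c("sparse", "border", "common"))

  expect_equal(p$status[p$species == "sparse"], "not_fit")
  expect_true(p$status[p$species == "border"] != "not_fit")
  # zeros for the full roster enter the fit
  expect_equal(unique(p$n_tows), 6L)
  expect_equal(p$mu[p$species == "common"], 12 / 6)

  # individuals reading of the filter: 7 individuals in 2 tows now passes
  p2 <- fit_yearly_params(tab, c("sparse", "border", "common"),
                          filter = "individuals")
  expect_true(p2$status[p2$species == "sparse"] != "not_fit")

  expect_error(fit_yearly_params(tab, c("common", "ghost")),
               "not present")
})

test_that("median_params uses per-parameter medians over ok years", {
  p <- data.frame(region = "R", year = c(1, 2, 3, 4),
                  species = "a",
                  mu = c(1, 2, 9, 50), k = c(4, 1, 2, 0.1),
                  status = c("ok", "ok", "ok", "not_fit"))
  m <- median_params(p)
  expect_equal(m$mu, 2)   # median of {1, 2, 9}; not_fit year excluded
  expect_equal(m$k, 2)    # medians taken independently per parameter

  # even year count: midpoint convention
  p$status <- "ok"
  p$mu <- c(1, 2, 3, 4)
  expect_equal(median_params(p)$mu, 2.5)

  # singleton
  expect_equal(median_params(p[2, ])$mu, 2)

  # invariant to year ordering
  expect_equal(median_params(p[c(3, 1, 4, 2), ]), median_params(p))

  two <- rbind(p, transform(p, species = "b", status = "not_fit"))
  expect_warning(m2 <- median_params(two), "no ok-status year")
  expect_equal(m2$species, "a")
})

test_that("parameter_trend reduces to MK on the yearly cross-species mean", {
  years <- 1:6
  p <- do.call(rbind, lapply(years, function(yr)
    data.frame(region = "R", year = yr, species = c("a", "b"),
               mu = yr * c(1, 2), k = c(1, 1), status = "ok")))
  tr <- parameter_trend(p, "R", "mu")
  expect_equal(tr$tau, 1)            # strictly increasing means
  expect_equal(tr$series$value, years * 1.5)
  trk <- parameter_trend(p, "R", "k")
  expect_equal(trk$tau, 0)           # constant means
  expect_equal(trk$p_value, 1)

  # boundary_k fits contribute to the mu mean but not to the k mean
  p$status[p$species == "b"] <- "boundary_k"
  expect_equal(parameter_trend(p, "R", "mu")$series$value, years * 1.5)
  expect_equal(parameter_trend(p, "R", "k")$series$n_species, rep(1L, 6))

  expect_error(parameter_trend(p[p$year < 3, ], "R", "mu"), "3 usable")
  expect_error(parameter_trend(p, "nowhere", "mu"), "unknown region")
})

test_that("parameter tables survive a CSV round trip", {
  p <- constant_param_table(4, 2001:2003, seed = 5)
  class(p) <- c("param_table", "data.frame")
  f <- withr::local_tempfile(fileext = ".csv")
  write_param_table(p, f)
  back <- read_param_table(f)
  expect_equal(back$mu, p$mu)
  expect_equal(back$species, p$species)
})
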