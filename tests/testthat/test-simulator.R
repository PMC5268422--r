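ref_params <- function() {
  data.frame(species = c("patchy", "common", "poissonish"),
             mu = c(0.4, 6, 4), k = c(0.3, 1.2, 1e4),
             status = c("ok", "ok", "boundary_k"))
}

test_that("simulate_community draws from the scheduled distributions", {
  m <- simulate_community(ref_params(), n_sites = 10000, seed = 5)
  expect_equal(dim(m), c(3, 10000))
  expect_true(all(m >= 0))

  # CLT bound on the row mean: se = sqrt((mu + mu^2/k)/n)
  se <- sqrt((0.4 + 0.4^2 / 0.3) / 10000)
  expect_lt(abs(mean(m["patchy", ]) - 0.4), 3 * se)

  # boundary_k rows are Poisson: variance ~ mean
  expect_lt(abs(var(m["poissonish", ]) - 4), 0.4)

  # determinism and row-order invariance (species sorted by label)
  m2 <- simulate_community(ref_params(), n_sites = 10000, seed = 5)
  expect_identical(m, m2)
  m3 <- simulate_community(ref_params()[c(3, 1, 2), ], n_sites = 10000,
                           seed = 5)
  expect_identical(m, m3)

  # not_fit species are omitted; fewer than 2 usable species errors
  p <- ref_params()
  p$status[1] <- "not_fit"
  expect_equal(nrow(simulate_community(p, 50, seed = 1)), 2)
  p$status[2:3] <- "not_fit"
  expect_error(simulate_community(p, 50, seed = 1), "fewer than 2")
})

test_that("sample_survey draws sites uniformly without replacement", {
  m <- simulate_community(ref_params(), n_sites = 300, seed = 2)
  s <- sample_survey(m, 55, seed = 9)
  expect_equal(dim(s), c(3, 55))
  ids <- attr(s, "site_ids")
  expect_false(any(duplicated(ids)))
  expect_true(all(colSums(s) %in% colSums(m)))

  # exhaustive sampling is a column permutation
  full <- sample_survey(m, 300, seed = 9)
  expect_equal(sort(colSums(full)), sort(colSums(m)))
  expect_error(sample_survey(m, 301, seed = 1), "exceeds")

  # selection frequency matches the binomial expectation
  n_rep <- 2000
  hits <- integer(300)
  for (r in seq_len(n_rep)) {
    idx <- attr(sample_survey(m, 30, seed = r), "site_ids")
    hits[idx] <- hits[idx] + 1L
  }
  p_exp <- 30 / 300
  se <- sqrt(p_exp * (1 - p_exp) / n_rep)
  expect_true(all(abs(hits / n_rep - p_exp) < 5 * se))
})

test_that("survey-of-community sampling is distributionally equivalent to direct draws", {
  n_rep <- 400
  means_pipe <- numeric(n_rep)
  params <- data.frame(species = c("a", "b"), mu = 2, k = 0.8,
                       status = "ok")
  for (r in seq_len(n_rep)) {
    comm <- simulate_community(params, n_sites = 1000, seed = 5000 + r)
    s <- sample_survey(comm, 55, seed = 9000 + r)
    means_pipe[r] <- mean(s["a", ])
  }
  set.seed(123)
  means_direct <- vapply(seq_len(n_rep),
                         function(i) mean(rnbinom(55, size = 0.8, mu = 2)),
                         0)
  ks <- suppressWarnings(ks.test(means_pipe, means_direct))
  expect_gt(ks$p.value, 0.01)
})

test_that("lowering k at fixed mu lowers expected sampled occupancy", {
  occ_at_k <- function(k) {
    params <- data.frame(species = c("x", "y"), mu = 2, k = k,
                         status = "ok")
    mean(vapply(1:100, function(r) {
      comm <- simulate_community(params, n_sites = 500,
                                 seed = r + round(1000 * k))
      occupancy(sample_survey(comm, 55, seed = r))[["x"]]
    }, 0))
  }
  occ <- vapply(c(5, 1, 0.3, 0.1), occ_at_k, 0)
  expect_true(all(diff(occ) < 0))
})

test_that("run_monte_carlo is reproducible and honours its modes", {
  params <- constant_param_table(8, 2001:2006, seed = 14)
  cfg <- sim_config(n_sites = 400, n_tows = 40, n_iterations = 2,
                    seed = 7, mode = "baseline")
  r1 <- run_monte_carlo(params, "SYN", cfg)
  r2 <- run_monte_carlo(params, "SYN", cfg)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_equal(nrow(r1), 2 * 6 * 2)  # iterations x years x measures

  # removal of nothing reproduces the baseline values bitwise
  plain <- function(x) {
    d <- as.data.frame(x)
    attributes(d) <- attributes(d)[c("names", "row.names", "class")]
    d
  }
  cfg_rm <- cfg
  cfg_rm$mode <- "species_removal"
  cfg_rm$removed_species <- character(0)
  expect_identical(plain(run_monte_carlo(params, "SYN", cfg_rm)),
                   plain(r1))

  # unknown removal labels warn and are ignored
  cfg_rm$removed_species <- "ghost"
  expect_warning(r3 <- run_monte_carlo(params, "SYN", cfg_rm),
                 "ghost")
  expect_identical(plain(r3), plain(r1))

  # a real removal changes the result
  cfg_rm2 <- cfg
  cfg_rm2$mode <- "species_removal"
  cfg_rm2$removed_species <- "species_01"
  r4 <- run_monte_carlo(params, "SYN", cfg_rm2)
  expect_false(identical(r4$slope, r1$slope))

  # year window restriction
  r5 <- run_monte_carlo(params, "SYN", cfg, years = 2001:2003)
  expect_equal(sort(unique(r5$year)), 2001:2003)
  expect_error(run_monte_carlo(params, "SYN", cfg, years = 2001:2002),
               "fewer than 3")
})

test_that("constant_median mode nulls out imposed parameter trends", {
  # strongly trending yearly parameters
  years <- 2001:2010
  sp <- sprintf("s%02d", 1:10)
  set.seed(3)
  base_mu <- exp(runif(10, log(0.5), log(8)))
  params <- do.call(rbind, lapply(seq_along(years), function(t)
    data.frame(region = "R", year = years[t], species = sp,
               mu = base_mu * 1.3^(t - 1), k = 1, status = "ok")))
  cfg <- function(mode) sim_config(n_sites = 400, n_tows = 55,
                                   n_iterations = 10, seed = 11,
                                   mode = mode,
                                   abundance_measures = "GMA")
  base <- run_monte_carlo(params, "R", cfg("baseline"))
  const <- run_monte_carlo(params, "R", cfg("constant_median"))
  tau_of <- function(x) mean(iteration_trends(x,
                                              indices = "intercept")$tau)
  # rising mu drives the intercept up in the baseline; holding medians
  # leaves only sampling noise
  expect_gt(tau_of(base), 0.5)
  expect_lt(abs(tau_of(const)), 0.3)
})
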