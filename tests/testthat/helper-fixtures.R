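# Shared fixtures, built in code at test time.

# Two-year, three-species toy region: sp A total 100 caught in both years,
# sp B total 50 in one year, sp C total 100 in one year.
toy_catch <- function() {
  records <- data.frame(
    region = "toy",
    year = c(2000, 2000, 2001, 2000, 2001, 2001),
    tow = c("t1", "t2", "t1", "t3", "t2", "t3"),
    species = c("A", "A", "A", "B", "C", "C"),
    count = c(60, 30, 10, 50, 70, 30))
  roster <- expand.grid(region = "toy", year = c(2000, 2001),
                        tow = c("t1", "t2", "t3"),
                        stringsAsFactors = FALSE)
  catch_table(records, roster)
}

# Small random species x tows count matrix with mixed dispersion.
random_sample_matrix <- function(n_species, n_tows, seed) {
  set.seed(seed)
  mu <- exp(runif(n_species, log(0.2), log(10)))
  k <- exp(runif(n_species, log(0.3), log(4)))
  m <- matrix(0L, n_species, n_tows,
              dimnames = list(paste0("sp", seq_len(n_species)), NULL))
  for (i in seq_len(n_species)) {
    m[i, ] <- rnbinom(n_tows, size = k[i], mu = mu[i])
  }
  m
}

# Parameter table with constant per-species (mu, k) replicated over years:
# the fixed-parameter null community.
constant_param_table <- function(n_species, years, seed,
                                 mu_range = c(0.1, 20),
                                 k_range = c(0.2, 5), region = "SYN") {
  set.seed(seed)
  mu <- exp(runif(n_species, log(mu_range[1]), log(mu_range[2])))
  k <- exp(runif(n_species, log(k_range[1]), log(k_range[2])))
  sp <- sprintf("species_%02d", seq_len(n_species))
  do.call(rbind, lapply(years, function(yr) {
    out <- data.frame(region = region, year = yr, species = sp,
                      mu = mu, k = k, status = "ok",
                      stringsAsFactors = FALSE)
    out
  }))
}
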