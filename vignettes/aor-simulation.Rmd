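---
title: "Simulating abundance-occupancy relationship trends from negative binomial communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating abundance-occupancy relationship trends from negative binomial communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aortrend)
```

## The question this package addresses

The interspecific abundance-occupancy relationship (AOR) pairs, for every
species in a community-year, its occupancy $O$ (the proportion of sampled
locations where at least one individual was present) with its mean abundance
$A$. Two abundance measures are supported: **global mean abundance** (GMA),
total individuals divided by all sampled tows, and **local mean abundance**
(LMA), total individuals divided by occupied tows only. The two are linked
exactly through occupancy, $\mathrm{GMA} = \mathrm{LMA}\times O$, which is
why GMA-based AORs are constrained toward positive slopes while LMA-based
ones are not.

Tracked over the years of a long survey series, the yearly AOR regression

$$\arcsin\sqrt{O} = s\,\ln A + C$$

yields three indices of community state: the slope $s$ (how unequally
occupied habitat is spread across abundance levels), the intercept $C$
(community-wide habitat occupation) and $R^2$ (homogeneity of spatial
strategies). The package asks whether temporal trends in those indices can
be generated, and therefore explained, by nothing more than each species'
yearly spatial distribution — summarized by a negative binomial — and the
finite effort of the survey that observes it.

## The model

Catch counts of species $i$ across the tows of one region-year are modeled
as negative binomial with mean $\mu$ and aggregation (size) parameter $k$:

$$p(x) = \binom{x+k-1}{x}\left(\frac{k}{k+\mu}\right)^{k}
          \left(\frac{\mu}{k+\mu}\right)^{x},$$

with variance $\mu + \mu^2/k$. Small $k$ means a patchy, aggregated
distribution; $k \to \infty$ recovers the Poisson. The pipeline has five
stages, each an exported function:

1. **Community selection** (`selection_index`, `select_community`): species
   are ranked by $S = H_i/H_{max} + y_i/y_{tot}$ — relative total catch plus
   proportion of survey years present — and the top 30 form the community
   used for every year of a region. The index screens out rare species whose
   occupancy a survey estimates poorly. Ties are broken by species label so
   selection is deterministic.
2. **Yearly NB fitting** (`fit_yearly_params`, `fit_nb`): per species-year,
   counts are assembled over the *full* tow roster (zeros included — the
   roster is carried explicitly by `catch_table` for exactly this reason)
   and $(\mu, k)$ estimated by maximum likelihood. A species enters a year
   only if caught more than twice.
3. **Community simulation** (`simulate_community`): a species-by-sites
   matrix (default 10,000 sites) of independent NB draws per species from
   its fitted yearly parameters.
4. **Survey resampling** (`sample_survey`): 55 sites drawn uniformly
   without replacement emulate one year of trawl effort.
5. **Indices and trends** (`fit_aor`, `mann_kendall`, `aggregate_trends`):
   the yearly AOR regression per iteration, a Mann-Kendall test on each
   index's year series per iteration, and the across-iteration mean
   $\bar\tau$ with a percentile 95% interval. A mean trend is called
   significant when that interval excludes zero.

`run_monte_carlo` orchestrates stages 3-5 for 500 iterations (default), and
`run_experiment` chains everything from a catch table to CSV/JSON outputs.

## Parameters that matter

| parameter | default | units | why this value |
|---|---|---|---|
| `n_sites` | 10,000 | sites | large enough that the 55-tow subsample sees realistic catch variation; since sites are exchangeable, 55-of-10,000 sampling is distributionally equivalent to 55 direct NB draws (tested), so the value is not critical |
| `n_tows` | 55 | tows/year | within the range of yearly trawl effort of the fall survey being emulated |
| `n_iterations` | 500 | — | stabilizes $\bar\tau$ and its percentile interval |
| community size | 30 | species | enough points for a meaningful yearly regression while restricted to well-sampled species |
| `k_cap` | $10^4$ | — | underdispersed samples have no interior NB maximum; the fit is capped and flagged `boundary_k`, and simulation draws those species Poisson |
| `min_points` | 3 | species | an OLS line plus one residual degree of freedom; years failing this are dropped from trend series with a warning |

## Experiment modes

* **baseline** — each year simulated from that year's fitted parameters;
  trends in the indices then reflect genuine year-to-year change in spatial
  behavior plus sampling noise.
* **constant_median** (`median_params`) — every species held at its
  across-years median $(\mu, k)$; interspecific diversity is preserved but
  intraspecific change is removed, so this is the null experiment: any
  "trend" it produces is a false positive, and per-iteration Mann-Kendall
  tests should reject at the nominal 5% rate. The acceptance suite verifies
  this calibration.
* **species_removal** — the baseline minus a named species list. The
  shipped list `gom_aggregating_species` holds the seven
  schooling/aggregating species of the Gulf of Maine case study (alewife,
  American shad, Atlantic argentine, Atlantic herring, longfin squid,
  northern shortfin squid, sea scallop) over 1973-1982; removing a rising
  block of high-abundance, low-occupancy species should shrink the
  magnitude of slope and $R^2$ trends, and does so on the synthetic
  case-study scenario.

## What the synthetic generator emulates — and what it does not

`generate_survey` draws catch tables with known structure: per-species NB
counts at every tow, geometric (multiplicative) yearly trajectories of
$\mu$ and $k$, optional intermittent presence (`presence_prob`, exercising
the inclusion-filter and not-fit pathways), and an optional aggregator
block whose $\mu$ ramps up while $k$ falls after a change year.
Trajectories are geometric so both parameters stay positive and imposed
trends are exactly monotonic — convenient for sign assertions. Default
conditions mirror the empirical survey shape: 45 years, 30 species, 55
tows/year, base parameters log-uniform over $\mu \in [0.1, 20]$
individuals/tow and $k \in [0.2, 5]$, spanning rare-to-dominant and
strongly-aggregated-to-near-random species.

The generator deliberately omits features of the real survey: no depth
stratification or area-proportional effort weighting (tows are treated as
exchangeable), no spatial coordinates or autocorrelation between sites, no
gear-selectivity or catchability change, no species interactions. Passing
tests therefore show that the *pipeline* is correct and calibrated under
NB assumptions — not that real communities are NB-distributed, which is a
modeling premise, not a test outcome.

## Numerical choices

* **NB likelihood maximization.** The MLE of $\mu$ is the sample mean for
  any $k$, so `fit_nb` maximizes the profile log-likelihood in $\log k$
  with `stats::optimize` (tolerance $10^{-8}$) over $k \in [10^{-4},
  k_{cap}]$. Samples with variance at or below the mean short-circuit to
  the `boundary_k` cap. Tests check the optimum against a brute-force grid
  and against the classical ML fit.
* **Mann-Kendall formulation.** Score $S = \sum_{i<j}
  \mathrm{sign}(x_j - x_i)$, Kendall's $\tau_b$ with tie correction,
  normal-approximation p-value with tie-adjusted variance and continuity
  correction. All-tied series return $\tau = 0$, $p = 1$. Missing years
  are dropped, not interpolated: the test is rank-based, so only order
  matters. The null rejection rate at series length 45 is verified at
  5% ± 1% over 10,000 replicates.
* **Occupancy transform.** "Arcsine-transformed occupancy" is implemented
  as $\arcsin\sqrt{O}$, the standard variance-stabilizing transform for
  proportions; $O = 1$ maps to $\pi/2$ exactly so no clamping is needed.
  A plain $\arcsin O$ variant sits behind `transform = "asin"` since the
  wording is ambiguous in parts of the AOR literature.
* **Exclusions from the regression.** Species with zero sampled catch have
  undefined $\ln A$ and are excluded from that year's fit; `n_points` is
  recorded so heavily-excluded years can be filtered downstream. Years
  with occupancy constant across species return slope 0 and $R^2$ 0
  (the regression indexes nothing there).
* **"Caught more than twice".** Interpreted as present in ≥ 3 tows of the
  region-year (default); the alternative reading, ≥ 3 total individuals,
  is available via `filter = "individuals"`. The tow reading is stricter
  and ties the filter to occupancy information.
* **Medians.** `median_params` takes medians independently per parameter
  over `ok`-status years, midpoint convention for even counts. Yearly
  cross-species parameter means (`parameter_trend`) use `ok` plus
  `boundary_k` fits for $\mu$ (the mean is a valid estimate at the
  boundary) but `ok` only for $k$ (the cap is censoring, not an estimate).
* **Reproducibility.** One root seed; per-(iteration, year, species)
  substreams via `substream_seed` (a multiplicative congruential hash kept
  exact in double arithmetic), so identical configs are bitwise
  reproducible and any slice can be regenerated alone. The empty-removal
  experiment reproduces the baseline bitwise under the same seed.

## Problem sizes used in the shipped checks

The test and acceptance runs scale the study design down to desk scale
while keeping the structure intact: the null-calibration run uses 30
species × 45 years × 2,000 sites × 55 tows × 200 iterations; the
slope-positivity run 500 iterations × 10 years × 1,000 sites; the
case-study contrast 100 iterations × 10 years × 1,000 sites. Because
55-of-$n$ subsampling is distributionally equivalent to direct 55-site
draws once $n \gg 55$, shrinking the site pool from 10,000 leaves the
sampling distribution of every index essentially unchanged while keeping
runtimes in minutes.

## Worked example

A self-contained run on synthetic data:

```{r example, eval = FALSE}
cfg <- scenario_config(n_years = 20, n_species = 30, tows_per_year = 55,
                       seed = 42)
tab <- generate_survey(cfg)

scores <- selection_index(tab, "region_01")
community <- select_community(scores, n = 30)
params <- fit_yearly_params(tab, community)

parameter_trend(params, "region_01", "mu")

sim <- run_monte_carlo(params, "region_01",
                       sim_config(n_sites = 2000, n_tows = 55,
                                  n_iterations = 100, seed = 1))
aggregate_trends(iteration_trends(sim))
ys <- yearly_summary(sim)
plot_yearly_summary(ys, "slope", "GMA")
```

## Known limitations

* Tows are exchangeable samples; survey designs with stratified effort
  need design-based expansion before ingestion, which is out of scope.
* The NB is the only count model offered — no zero-inflated or
  Poisson-lognormal alternatives, and no covariate-dependent (GLM)
  fitting.
* The AOR regression is an index, not a mechanism: no metapopulation or
  Poisson-null occupancy models are fitted.
* Mann-Kendall is the plain form; no Sen's slope, no
  autocorrelation-corrected variants.
* When no tow roster is supplied, effort is inferred from observed
  records and is understated if some tow caught none of the ingested
  species — supply the roster file when available.
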