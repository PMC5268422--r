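Package: aortrend
Title: Abundance-Occupancy Relationship Trends from Simulated Survey Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study temporal trends in interspecific
    abundance-occupancy relationships (AORs) from bottom-trawl survey catch
    data. Fits yearly negative binomial distributions (mean mu, aggregation k)
    to per-tow counts of each species, simulates communities by Monte Carlo
    from the fitted parameters, resamples a survey of fixed effort from each
    simulated community, computes yearly AOR regression indices (slope,
    intercept, R-squared) under global or local mean abundance, and tests and
    aggregates Mann-Kendall trends across simulation iterations. Includes a
    synthetic survey generator with controllable parameter trajectories, a
    constant-parameter null experiment, and a species-removal case study.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
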