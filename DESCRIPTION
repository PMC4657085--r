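Package: torospool
Title: Toroidal-Spool Mechanics of Circular DNA and Nucleoid Cluster Analysis
Version: 0.1.0
Authors@R: person("torospool", "maintainers", email = "maintainers@torospool.org",
    role = c("aut", "cre"))
Description: Worm-like-chain energetics of circular DNA arranged into toroidal
    spools, platinum-adduct stress bookkeeping, a closed elastic-rod Metropolis
    Monte-Carlo simulator with writhe/twist/linking-number accounting, a
    density-based cluster pipeline for single-molecule localization (PALM) data
    from spherocylindrical bacterial cells, and seeded synthetic-data
    generators that emulate the statistical structure of adduct time series and
    HNS-cluster localization sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
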