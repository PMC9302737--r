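Package: gridpopsim
Title: Simulation-Based Cell-Level Accuracy Assessment of Top-Down Gridded
    Population Estimates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how census outdatedness, undercount, and areal
    aggregation propagate into cell-level error of top-down dasymetric
    population rasters. Generates a stratified synthetic household population
    (urban slum, urban non-slum, rural) on a 100 m grid together with nested
    enumeration-area- and constituency-like zone tilings and synthetic
    covariate layers of mixed native resolution; degrades the population into
    outdated and undercounted census scenarios; disaggregates each census with
    a random-forest density model and pycnophylactic (mass-preserving)
    normalisation; and evaluates population-adjusted RMSE, density RMSE, bias,
    relative bias, and the fraction of population misallocated to unsettled
    cells, at block-aggregated scales from 100 m to 1 km and by stratum.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    ranger,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
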