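---
title: "Methods: simulating cell-level accuracy of top-down gridded population estimates"
author: "gridpopsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating cell-level accuracy of top-down gridded population estimates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Top-down gridded population datasets disaggregate census counts from areal
units (enumeration areas, districts) to small grid cells using a statistical
model and spatial covariates. Their accuracy is usually assessed at the scale
of the input units — the finest scale at which reference counts exist — while
users apply them at the cell or neighbourhood scale. `gridpopsim` builds a
controlled laboratory for that gap: it simulates a "true" household
population whose every person has a known location, turns it into the kind of
census a statistics office would actually hold (outdated by 0–15 years,
undercounted most heavily in slums, aggregated to areal units), runs a
WorldPop-style unconstrained random-forest dasymetric model on each census,
and measures cell-level error against the known truth.

# The synthetic study region

The default configuration (`simConfig()`) emulates a majority-urban,
Khomas-like region on a 360 x 360 grid of 100 m cells (36 x 36 km, 1 cell =
1 ha):

* **Stratum geography.** A circular city of radius 45 cells (~5% of the grid
  area) sits at the grid centre. Inside it, 4 seeded blobs of radius 11
  cells form the urban-slum stratum; the remaining urban cells are non-slum;
  everything outside the city is rural and almost entirely unsettled.
* **Households.** 35,001 urban-slum, 57,843 urban-non-slum and 4,823 rural
  households (the 2016 stratum totals of the emulated region). Slum
  households are drawn with Gaussian density weights around the patch cores
  (`densityDecay` = 0.6 patch radii), non-slum households with a broader
  Gaussian around the city centre, rural households uniformly over the
  hinterland. Points are jittered uniformly within their cell.
* **Household size.** The region's censuses report household counts, not a
  size distribution, so sizes are a modelling assumption: a lognormal with
  mean 4.0 persons and log-scale sd 0.45, integerised without bias
  (`floor(X) + Bernoulli(frac(X))`) and truncated below at 1 person. The
  truncation affects ~0.2% of draws, so the realised mean stays within
  Monte-Carlo error of 4.0.
* **Build years.** Cumulative household counts per stratum for 2001, 2006,
  2011 and 2016 default to the emulated region's censal growth
  (urban-slum 13,149 / 18,018 / 28,583 / 35,001). Because outdatedness is
  modelled as pure removal, year counts must be non-decreasing; the rural
  series is therefore capped at its current value (3,731 / 4,146 / 4,823 /
  4,823) where the source region actually recorded a small rural decline
  between 2011 and 2016 — a pattern removal-only filtering cannot express.
  Within each stratum the oldest cohorts are placed nearest the stratum
  centroid and newer cohorts toward the fringe (score = centroid distance +
  Gaussian jitter of 0.25 spatial spreads), emulating outward urban growth.
* **Zones.** Settled cells are ordered along a Morton (Z-order) curve and
  cut into 922 small zones of near-equal household counts; unsettled cells
  join their nearest settled zone via a deterministic flood fill; 10 large
  zones group consecutive small zones. The construction is deterministic,
  balanced (max/min household ratio well under 5) and exactly nested. Runs
  of a Z-order curve are not guaranteed 4-connected at quadrant boundaries,
  so strict connectivity is documented as approximate rather than asserted.
* **Covariates.** Each layer is
  `informativeness * g(blockmean_f(log1p(density))) + noiseSd * eps`, with
  the block mean and noise drawn per `nativeFactor` x `nativeFactor` block.
  This makes coarse layers exactly block-constant, reproducing the
  "halo" mechanism by which a ~900 m covariate smears settlement signal into
  unsettled cells ringing a town. The default suite mixes fine
  distance-style layers (factor 1, negative link), ~300 m land-cover-style
  layers (factor 3), and ~900 m night-lights/travel-time-style layers
  (factor 9). What the generator does *not* emulate: temporal mismatch
  between covariates and census, spatial autocorrelation of covariate
  *errors*, non-residential buildings, multi-city geographies. Passing tests
  therefore demonstrate properties of the method, not accuracy guarantees
  for any real region.

# Census degradation

Sixteen census scenarios cross four reference years (0-, 5-, 10-, 15-years
outdated, via `filterByYear()`) with four undercount levels
(`applyUndercount()`): none, low (10% of slum and 2% of non-slum/rural
households missing), medium (30%/5%), high (60%/10%). Removal is uniformly
random within stratum — deliberately free of spatial pattern — and retains
exactly `floor((1-r) * N)` households, the rounding rule that reproduces the
emulated region's published slum household table cell-for-cell. The region's
published non-slum and rural columns are consistent with the two strata
being *pooled* during removal (their sums match the pooled floor exactly
while the per-stratum floors do not); both behaviours are implemented
(`pooledUndercount`), with independent removal as the default. Each degraded
population is aggregated to both zone levels (`makeCensus()`), giving 32
census inputs and, after modelling, 32 gridded datasets.

# The dasymetric model

`gridpopsim` re-implements the unconstrained three-phase workflow:

* **Phase A** (`zonalFeatures()`, `trainDensityModel()`): per input zone,
  covariate means and the log of census population density (population /
  zone area in hectares; the *whole* zone area, not only settled cells —
  the unconstrained behaviour under study). Zones with zero population have
  no log density and are excluded from training. A regression forest
  (`ranger`) with 500 bootstrap trees, `ceiling(p/3)` candidate covariates
  per split and unlimited depth is fit to these zonal records; the
  hyperparameters are conventional regression-forest defaults and fully
  configurable.
* **Phase B** (`predictDensity()`): per-cell density is
  `exp(mean over trees of predicted log density)` — strictly positive in
  every cell, settled or not. No smearing correction is applied to the
  back-transform: the wording of the source workflow does not specify one,
  and phase C cancels any zone-constant factor anyway.
* **Phase C** (`disaggregate()`): within each zone the census population is
  distributed proportionally to predicted density, making the estimate
  pycnophylactic (per-zone sums reproduce the census to ~1e-15 relative
  error; asserted at 1e-9). Normalisation happens on the natural scale —
  the only scale on which mass conservation is meaningful. Zero-population
  zones get zero cells; a zero-density zone with positive population (never
  observed under the defaults) falls back to uniform disaggregation with a
  warning.

With single-cell zones the normalisation dominates completely and the
estimate equals the census raster regardless of covariates — a useful
identifiability check, and the reason finer training data helps.

# Evaluation

`stratifyAndReport()` computes, at block-aggregation factors k = 1..10
(100 m to 1 km; ragged edge blocks dropped, which loses no mass on the
default 360-divisible grid):

* population-adjusted RMSE: `sqrt(mean((est - truth)^2)) / mean(truth)`;
* density RMSE in persons/ha: block counts divided by k² hectares;
* bias `mean(est - truth)` (negative = under-estimate) and relative bias;
* the percent of the estimated population misallocated to cells that are
  unsettled in the truth.

Cells with an aggregated *estimate* below 1 person are excluded from the
RMSE/bias statistics, applied at the evaluated scale (the source rule states
the threshold but not the scale at which it binds after aggregation; binding
it after aggregation keeps the rule meaningful at every scale).
Misallocation never applies the threshold — near-zero estimates in unsettled
cells are exactly what it measures; on grids the factor divides it is
provably non-increasing in k (a block is unsettled iff all its sub-cells
are). Each aggregated cell takes the stratum holding the plurality of its
true population, ties broken slum > non-slum > rural (slum error is the
phenomenon of interest); blocks with no true population take the plurality
of their stratum-map labels, so coarse-covariate halo cells around the city
are evaluated as urban. Rows whose mask is empty (e.g. rural cells all below
the threshold at 100 m) are reported as NA with `n_cells` 0 rather than
dropped, keeping the report shape fixed.

# Reproducibility and numerical choices

One master seed drives everything; each operation (and each scenario's
forest and undercount draw) derives an independent substream keyed by
operation name, so any single scenario rerun in isolation is byte-identical
to its slice of a full run, and the "none" scenario is identical across
aggregation levels. Forests run single-threaded with a fixed seed. The
retained-count formula adds 1e-9 before flooring to guard against binary
fraction representation (e.g. `0.7 * N` evaluating a hair under an integer).
Coordinates are metres with half-open cells (closed top and left edges, row
0 at the top); a point on a shared edge belongs to exactly one cell.

Problem sizes were chosen to keep a full 32-scenario run of the default
configuration at a few minutes on one core: unit tests run on a 60 x 60
scaled-down region with the same structure, and the full-size default is
exercised by the acceptance checks and `scripts/acceptance.R`.

# Known limitations

* One region shape (single city), one covariate family, one forest
  configuration; results are mechanism demonstrations, not forecasts for
  any real place.
* The published error magnitudes of the study this design emulates depend
  on that region's real population and covariates and are not reproduced
  here; the package reproduces the arithmetic of the census tables, the
  conservation and monotonicity properties, and the sign/ordering of the
  slum under-estimation phenomenon.
* Uncertainty quantification is out of scope (the source workflow computes
  it only at areal-unit scale), as are constrained (settlement-masked)
  variants and person-level (intra-household) undercount.
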