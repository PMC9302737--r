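#' @import methods
NULL

#' Population strata
#'
#' Stratum labels used throughout the package, in tie-break priority order:
#' urban slum, urban non-slum, rural.
#' @export
STRATA <- c("urban_slum", "urban_nonslum", "rural")

#' Census inaccuracy levels and their per-stratum undercount rates
#'
#' Proportion of households removed per stratum at each simulated inaccuracy
#' level: low removes 10% of urban-slum and 2% of urban-non-slum and rural
#' households; medium 30% / 5% / 5%; high 60% / 10% / 10%; none removes
#' nothing.
#' @export
UNDERCOUNT_RATES <- list(
  none   = c(urban_slum = 0.00, urban_nonslum = 0.00, rural = 0.00),
  low    = c(urban_slum = 0.10, urban_nonslum = 0.02, rural = 0.02),
  medium = c(urban_slum = 0.30, urban_nonslum = 0.05, rural = 0.05),
  high   = c(urban_slum = 0.60, urban_nonslum = 0.10, rural = 0.10)
)

# ---------------------------------------------------------------- GridSpec --

#' GridSpec: geometry of the analysis grid
#'
#' Describes a regular square-celled grid in metres. Cells are half-open
#' squares: column c (0-based) spans `[originX + c*s, originX + (c+1)*s)` and
#' row r (0-based, row 0 at the TOP) spans `(originY - (r+1)*s, originY - r*s]`,
#' where `s` is the cell size. `originX`/`originY` are therefore the top-left
#' corner. Every raster in a run shares one GridSpec.
#'
#' @slot originX,originY top-left corner, metres
#' @slot cellSize cell edge length, metres (default 100, i.e. 1 cell = 1 ha)
#' @slot nRows,nCols grid dimensions
#' @export
setClass("GridSpec",
  slots = c(originX = "numeric", originY = "numeric", cellSize = "numeric",
            nRows = "integer", nCols = "integer"))

setValidity("GridSpec", function(object) {
  msg <- character()
  for (s in c("originX", "originY", "cellSize"))
    if (length(slot(object, s)) != 1L || !is.finite(slot(object, s)))
      msg <- c(msg, sprintf("'%s' must be a single finite number", s))
  if (length(object@cellSize) == 1L && !is.na(object@cellSize) &&
      object@cellSize <= 0)
    msg <- c(msg, "'cellSize' must be > 0")
  if (length(object@nRows) != 1L || is.na(object@nRows) || object@nRows < 1L)
    msg <- c(msg, "'nRows' must be a positive integer")
  if (length(object@nCols) != 1L || is.na(object@nCols) || object@nCols < 1L)
    msg <- c(msg, "'nCols' must be a positive integer")
  if (length(msg)) msg else TRUE
})

# -------------------------------------------------------------- grid layers --

#' Virtual parent of all gridded layers
#'
#' Holds a value matrix (`nRows` x `nCols`, row 1 = top row) plus its GridSpec.
#' @slot values matrix of per-cell values
#' @slot grid a [GridSpec-class]
#' @export
setClass("GridLayer", representation("VIRTUAL",
  values = "matrix", grid = "GridSpec"))

setValidity("GridLayer", function(object) {
  g <- object@grid
  if (nrow(object@values) != g@nRows || ncol(object@values) != g@nCols)
    return(sprintf("values matrix is %dx%d but grid is %dx%d",
                   nrow(object@values), ncol(object@values), g@nRows, g@nCols))
  TRUE
})

#' PopGrid: a per-cell population (or density) raster
#'
#' @slot values numeric matrix of per-cell person counts (role "truth" or
#'   "estimate") or persons per hectare (role "density")
#' @slot role one of "truth", "estimate", "density"
#' @export
setClass("PopGrid", contains = "GridLayer", slots = c(role = "character"))

setValidity("PopGrid", function(object) {
  if (!is.numeric(object@values)) return("'values' must be numeric")
  if (any(!is.finite(object@values))) return("'values' must be finite")
  if (any(object@values < 0)) return("'values' must be non-negative")
  if (length(object@role) != 1L ||
      !object@role %in% c("truth", "estimate", "density"))
    return("'role' must be one of 'truth', 'estimate', 'density'")
  TRUE
})

#' StratumGrid: per-cell stratum labels
#'
#' Integer codes index into [STRATA] (1 = urban_slum, 2 = urban_nonslum,
#' 3 = rural); the whole grid is covered.
#' @export
setClass("StratumGrid", contains = "GridLayer")

setValidity("StratumGrid", function(object) {
  v <- object@values
  if (!is.numeric(v) || any(!(v %in% seq_along(STRATA))))
    return("stratum codes must all be in 1..3")
  TRUE
})

#' ZoneMap: per-cell areal-unit labels
#'
#' Labels are contiguous integers `1..K`; every cell is labelled. `level`
#' records whether the tiling emulates small census zones (enumeration areas)
#' or large administrative zones (constituencies).
#' @slot level "small_zone" or "large_zone"
#' @export
setClass("ZoneMap", contains = "GridLayer", slots = c(level = "character"))

setValidity("ZoneMap", function(object) {
  v <- object@values
  if (any(is.na(v)) || any(v < 1) || any(v != round(v)))
    return("zone labels must be positive integers covering every cell")
  k <- max(v)
  if (!all(seq_len(k) %in% v)) return("zone labels must be contiguous 1..K")
  if (length(object@level) != 1L ||
      !object@level %in% c("small_zone", "large_zone"))
    return("'level' must be 'small_zone' or 'large_zone'")
  TRUE
})

#' CovariateLayer: one synthetic ancillary raster
#'
#' A covariate layer is generated as
#' `informativeness * g(blockmean_f(log1p(density))) + noiseSd * eps_block`,
#' where block means and the Gaussian noise are taken over `nativeFactor` x
#' `nativeFactor` cell blocks, so the layer is exactly constant within each
#' native block — emulating covariates whose original resolution is coarser
#' than the output grid (e.g. ~900 m night-time lights on a 100 m grid).
#'
#' @slot name layer name
#' @slot nativeFactor native resolution as a multiple of the grid cell size
#' @slot informativeness weight in `[0,1]` on the density signal (0 = pure
#'   noise)
#' @slot noiseSd standard deviation of the per-block noise
#' @slot link monotone link applied to the block-averaged signal:
#'   "identity" or "negative" (sign flip, emulating distance-to-feature
#'   layers that decrease with density)
#' @export
setClass("CovariateLayer", contains = "GridLayer",
  slots = c(name = "character", nativeFactor = "integer",
            informativeness = "numeric", noiseSd = "numeric",
            link = "character"))

setValidity("CovariateLayer", function(object) {
  msg <- character()
  if (any(!is.finite(object@values))) msg <- c(msg, "values must be finite")
  if (object@nativeFactor < 1L) msg <- c(msg, "'nativeFactor' must be >= 1")
  if (object@informativeness < 0 || object@informativeness > 1)
    msg <- c(msg, "'informativeness' must be in [0,1]")
  if (object@noiseSd < 0) msg <- c(msg, "'noiseSd' must be >= 0")
  if (!object@link %in% c("identity", "negative"))
    msg <- c(msg, "'link' must be 'identity' or 'negative'")
  if (length(msg)) msg else TRUE
})

#' CovariateStack: named collection of aligned covariate layers
#' @slot layers list of [CovariateLayer-class], all sharing `grid`
#' @export
setClass("CovariateStack",
  slots = c(layers = "list", grid = "GridSpec"))

setValidity("CovariateStack", function(object) {
  if (!length(object@layers)) return("stack must contain at least one layer")
  ok <- vapply(object@layers, function(l) is(l, "CovariateLayer"), logical(1))
  if (!all(ok)) return("all elements of 'layers' must be CovariateLayer")
  nm <- vapply(object@layers, function(l) l@name, character(1))
  if (anyDuplicated(nm)) return("layer names must be unique")
  same <- vapply(object@layers, function(l) identical(l@grid, object@grid),
                 logical(1))
  if (!all(same)) return("all layers must share the stack's GridSpec")
  TRUE
})

# ------------------------------------------------------------ DensityModel --

#' DensityModel: a trained random-forest density model
#'
#' Wraps a regression forest fitted to zonal covariate means against
#' log population density (persons per hectare), together with the training
#' metadata needed for reproducible prediction.
#'
#' @slot forest the fitted `ranger` object
#' @slot covariateNames covariates (in training order)
#' @slot excludedZones ids of zero-population zones excluded from training
#' @slot seed RNG seed used for the forest
#' @slot settings list with `numTrees` and `mtry`
#' @export
setClass("DensityModel",
  slots = c(forest = "ANY", covariateNames = "character",
            excludedZones = "integer", seed = "integer", settings = "list"))

# -------------------------------------------------------- SimulationConfig --

#' SimulationConfig: parameters of the synthetic study region
#'
#' Defaults emulate a Khomas-like region in 2016: a dense city covering about
#' 5% of a 36 x 36 km grid, 35,001 urban-slum / 57,843 urban-non-slum / 4,823
#' rural households, outward urban growth over 2001-2016, 922 small and 10
#' large census zones, and covariates of mixed native resolution. Use
#' [simConfig()] to construct.
#'
#' @slot grid the analysis [GridSpec-class]
#' @slot counts named current (final-year) household counts per stratum
#' @slot years census reference years, increasing
#' @slot yearCounts matrix `length(years)` x 3 of cumulative household counts
#'   per stratum; non-decreasing down each column, final row equals `counts`
#' @slot meanHouseholdSize,sdLogHouseholdSize mean and log-scale sd of the
#'   truncated-lognormal household size distribution
#' @slot cityCentre fractional (x, y) position of the city centre in the grid
#' @slot cityRadius city radius, in cells
#' @slot nSlumPatches,slumPatchRadius number and radius (cells) of slum blobs
#' @slot densityDecay within-patch density decay length as a fraction of the
#'   patch radius (smaller = sharper density peaks)
#' @slot maxPerCell capacity cap: maximum mean households per cell per stratum
#' @slot yearJitter sd of the fringe-growth noise, as a fraction of the
#'   stratum's spatial spread
#' @slot nSmall,nLarge number of small and large zones
#' @slot covariates list of covariate specs (see [covariateSpec()])
#' @slot numTrees,mtry random-forest settings (`mtry` NA = ceiling(p/3))
#' @slot pooledUndercount if TRUE, non-slum and rural households are pooled
#'   when removing undercounted households
#' @export
setClass("SimulationConfig",
  slots = c(grid = "GridSpec", counts = "numeric", years = "integer",
            yearCounts = "matrix", meanHouseholdSize = "numeric",
            sdLogHouseholdSize = "numeric", cityCentre = "numeric",
            cityRadius = "numeric", nSlumPatches = "integer",
            slumPatchRadius = "numeric", densityDecay = "numeric",
            maxPerCell = "numeric", yearJitter = "numeric",
            nSmall = "integer", nLarge = "integer", covariates = "list",
            numTrees = "integer", mtry = "integer",
            pooledUndercount = "logical"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (!identical(sort(names(object@counts)), sort(STRATA)))
    msg <- c(msg, "'counts' must be named by the three strata")
  if (any(object@counts < 0)) msg <- c(msg, "'counts' must be >= 0")
  if (is.unsorted(object@years, strictly = TRUE))
    msg <- c(msg, "'years' must be strictly increasing")
  yc <- object@yearCounts
  if (nrow(yc) != length(object@years) ||
      !identical(sort(colnames(yc)), sort(STRATA))) {
    msg <- c(msg, "'yearCounts' must be length(years) x 3 with stratum columns")
  } else {
    for (s in STRATA) {
      if (is.unsorted(yc[, s]))
        msg <- c(msg, sprintf("'yearCounts' for %s must be non-decreasing", s))
      if (yc[nrow(yc), s] != object@counts[[s]])
        msg <- c(msg, sprintf("final-year count for %s must equal counts", s))
    }
  }
  if (object@nSmall < object@nLarge || object@nLarge < 1L)
    msg <- c(msg, "need nSmall >= nLarge >= 1")
  if (object@meanHouseholdSize <= 1)
    msg <- c(msg, "'meanHouseholdSize' must exceed 1")
  if (length(msg)) msg else TRUE
})

# ------------------------------------------------------- EvaluationConfig --

#' EvaluationConfig: scales, inclusion threshold and strata for evaluation
#'
#' @slot scales integer block factors k; scale k compares (100*k) m cells
#' @slot threshold inclusion threshold in persons: aggregated estimate cells
#'   below it are excluded from RMSE/bias (default 1, the "<1 person" rule);
#'   misallocation ignores it
#' @slot strata stratum labels to report (an "all" row is always added)
#' @export
setClass("EvaluationConfig",
  slots = c(scales = "integer", threshold = "numeric", strata = "character"))

setValidity("EvaluationConfig", function(object) {
  if (any(object@scales < 1L)) return("'scales' must be >= 1")
  if (object@threshold < 0) return("'threshold' must be >= 0")
  if (!all(object@strata %in% STRATA)) return("unknown stratum label")
  TRUE
})
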