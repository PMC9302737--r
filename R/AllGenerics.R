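# Generics, accessors and show methods for the core classes.

#' Grid geometry of an object
#' @param x a grid layer, stack or config object
#' @return the object's [GridSpec-class]
#' @export
setGeneric("gridSpec", function(x) standardGeneric("gridSpec"))

#' Per-cell values of a grid layer
#' @param x a [GridLayer-class]
#' @return the value matrix (row 1 = top row)
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

#' Number of zones in a zone map
#' @param x a [ZoneMap-class]
#' @export
setGeneric("nZones", function(x) standardGeneric("nZones"))

#' Names of the layers in a covariate stack
#' @param x a [CovariateStack-class]
#' @export
setGeneric("layerNames", function(x) standardGeneric("layerNames"))

#' @describeIn gridSpec grid of a layer
#' @export
setMethod("gridSpec", "GridLayer", function(x) x@grid)

#' @describeIn gridSpec grid of a stack
#' @export
setMethod("gridSpec", "CovariateStack", function(x) x@grid)

#' @describeIn gridSpec grid of a simulation config
#' @export
setMethod("gridSpec", "SimulationConfig", function(x) x@grid)

#' @describeIn gridValues value matrix of any grid layer
#' @export
setMethod("gridValues", "GridLayer", function(x) x@values)

#' @describeIn nZones largest (= number of) zone label
#' @export
setMethod("nZones", "ZoneMap", function(x) as.integer(max(x@values)))

#' @describeIn layerNames layer names in stack order
#' @export
setMethod("layerNames", "CovariateStack",
  function(x) vapply(x@layers, function(l) l@name, character(1)))

#' Extract one layer from a covariate stack
#' @param x a [CovariateStack-class]
#' @param i layer name or index
#' @export
setMethod("[[", "CovariateStack", function(x, i) {
  if (is.character(i)) {
    j <- match(i, layerNames(x))
    if (is.na(j)) stop("no covariate layer named '", i, "'")
    i <- j
  }
  x@layers[[i]]
})

#' @describeIn CovariateStack-class number of layers
#' @param x a CovariateStack
#' @export
setMethod("length", "CovariateStack", function(x) length(x@layers))

setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: %d x %d cells of %gm, top-left (%g, %g)\n",
              object@nRows, object@nCols, object@cellSize,
              object@originX, object@originY))
})

setMethod("show", "PopGrid", function(object) {
  v <- object@values
  cat(sprintf("PopGrid (%s): %d x %d cells, total %.2f, %d settled cells\n",
              object@role, nrow(v), ncol(v), sum(v), sum(v > 0)))
})

setMethod("show", "StratumGrid", function(object) {
  tab <- tabulate(object@values, nbins = length(STRATA))
  cat("StratumGrid:",
      paste(sprintf("%s=%d", STRATA, tab), collapse = ", "), "cells\n")
})

setMethod("show", "ZoneMap", function(object) {
  cat(sprintf("ZoneMap (%s): %d zones over %d x %d cells\n", object@level,
              nZones(object), nrow(object@values), ncol(object@values)))
})

setMethod("show", "CovariateLayer", function(object) {
  cat(sprintf(
    "CovariateLayer '%s': native factor %d, informativeness %.2f, noise sd %.2f\n",
    object@name, object@nativeFactor, object@informativeness, object@noiseSd))
})

setMethod("show", "CovariateStack", function(object) {
  cat(sprintf("CovariateStack: %d layers on a %d x %d grid\n",
              length(object@layers), object@grid@nRows, object@grid@nCols))
  for (l in object@layers) show(l)
})

setMethod("show", "DensityModel", function(object) {
  cat(sprintf(
    "DensityModel: %d trees, mtry %d, %d covariates, %d zones excluded\n",
    object@settings$numTrees, object@settings$mtry,
    length(object@covariateNames), length(object@excludedZones)))
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig\n")
  cat(sprintf("  grid: %d x %d cells of %gm\n", object@grid@nRows,
              object@grid@nCols, object@grid@cellSize))
  cat("  households:",
      paste(sprintf("%s=%d", STRATA, object@counts[STRATA]), collapse = ", "),
      "\n")
  cat("  years:", paste(object@years, collapse = ", "), "\n")
  cat(sprintf("  zones: %d small / %d large\n", object@nSmall, object@nLarge))
  cat(sprintf("  covariates: %d layers; forest: %d trees\n",
              length(object@covariates), object@numTrees))
})

setMethod("show", "EvaluationConfig", function(object) {
  cat(sprintf(
    "EvaluationConfig: scales %s (x100m), threshold %g persons\n",
    paste(range(object@scales), collapse = "-"), object@threshold))
})
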