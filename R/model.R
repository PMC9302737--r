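# WorldPop-style three-phase dasymetric workflow: zonal features, a
# random-forest model of log population density, per-cell prediction, and
# pycnophylactic (mass-preserving) disaggregation.

#' Summarise covariates and census density by zone
#'
#' Phase A inputs: per zone, the mean of every covariate over the zone's
#' cells, the census population density (population / area in cells; 1 cell
#' = 1 ha), and its natural log. Zones with zero census population carry no
#' log density and are flagged `excluded` — they take no part in model
#' training.
#'
#' @param cov a [CovariateStack-class]
#' @param zones a [ZoneMap-class] on the same grid
#' @param census ZoneTable from [makeCensus()] covering all zone labels
#' @return data.frame with `zone_id`, one column per covariate, `density`,
#'   `log_density` (NA for excluded zones), `excluded`
#' @export
zonalFeatures <- function(cov, zones, census) {
  if (!identical(gridSpec(cov), gridSpec(zones)))
    stop("covariate stack and zone map are on different grids")
  lab <- as.vector(asValues(zones))
  k <- nZones(zones)
  if (!all(seq_len(k) %in% census$zone_id))
    stop("census must cover all zone labels")
  census <- census[match(seq_len(k), census$zone_id), ]
  cellCount <- tabulate(lab, nbins = k)
  feats <- data.frame(zone_id = seq_len(k))
  for (nm in layerNames(cov)) {
    v <- rowsum(as.vector(gridValues(cov[[nm]])), lab)
    feats[[nm]] <- v[, 1] / cellCount
  }
  feats$density <- census$population / census$area_cells
  feats$excluded <- census$population == 0
  feats$log_density <- ifelse(feats$excluded, NA_real_, log(feats$density))
  feats
}

#' Train the random-forest density model
#'
#' Phase A: fits a regression forest (bootstrap-resampled trees) to the
#' zonal covariate means against log population density, over non-excluded
#' zones only. Defaults are conventional regression-forest settings: 500
#' trees, `ceiling(p/3)` candidate covariates per split, unlimited depth.
#'
#' @param features output of [zonalFeatures()]
#' @param numTrees number of trees
#' @param mtry candidate covariates per split (NA = `ceiling(p/3)`)
#' @param seed RNG seed; the same seed and data give identical forests
#' @return a [DensityModel-class]
#' @export
trainDensityModel <- function(features, numTrees = 500L, mtry = NA_integer_,
                              seed = 1L) {
  covNames <- setdiff(names(features),
                      c("zone_id", "density", "log_density", "excluded"))
  if (!length(covNames)) stop("need at least one covariate")
  train <- features[!features$excluded, , drop = FALSE]
  if (nrow(train) < 2L)
    stop("need at least 2 zones with positive population to train (have ",
         nrow(train), ")")
  if (is.na(mtry)) mtry <- ceiling(length(covNames) / 3)
  dat <- train[, covNames, drop = FALSE]
  dat$log_density <- train$log_density
  forest <- ranger::ranger(
    dependent.variable.name = "log_density", data = dat,
    num.trees = as.integer(numTrees), mtry = as.integer(mtry),
    min.node.size = 5, replace = TRUE, seed = as.integer(seed),
    num.threads = 1)
  new("DensityModel", forest = forest, covariateNames = covNames,
      excludedZones = as.integer(features$zone_id[features$excluded]),
      seed = as.integer(seed),
      settings = list(numTrees = as.integer(numTrees),
                      mtry = as.integer(mtry)))
}

#' Out-of-bag R-squared of a trained density model
#' @param model a [DensityModel-class]
#' @export
oobRsquared <- function(model) model@forest$r.squared

#' Predict per-cell population density
#'
#' Phase B: for every cell, the prediction is the exponential of the mean
#' over trees of the predicted log density — strictly positive everywhere,
#' including unsettled cells (the unconstrained behaviour under study; no
#' settlement mask is applied).
#'
#' @param model a [DensityModel-class]
#' @param cov a [CovariateStack-class] containing all training covariates
#' @return a [PopGrid-class] with role "density" (persons per hectare)
#' @export
predictDensity <- function(model, cov) {
  missing <- setdiff(model@covariateNames, layerNames(cov))
  if (length(missing))
    stop("covariate(s) missing from the stack: ",
         paste(missing, collapse = ", "))
  g <- gridSpec(cov)
  newdata <- as.data.frame(lapply(model@covariateNames, function(nm)
    as.vector(gridValues(cov[[nm]]))))
  names(newdata) <- model@covariateNames
  pred <- stats::predict(model@forest, data = newdata,
                         num.threads = 1)$predictions
  new("PopGrid", values = matrix(exp(pred), g@nRows, g@nCols), grid = g,
      role = "density")
}

#' Dasymetric disaggregation with pycnophylactic normalisation
#'
#' Phase C: within each zone, the census population is distributed over
#' cells proportionally to the predicted density, so per-zone sums of the
#' estimate equal the census counts exactly (up to floating-point rounding).
#' Zones with zero census population get all-zero cells; a zone whose
#' predicted density sums to zero but has positive population falls back to
#' uniform disaggregation, with a warning.
#'
#' @param density per-cell density [PopGrid-class] from [predictDensity()]
#' @param zones a [ZoneMap-class] on the same grid
#' @param census ZoneTable covering all zone labels
#' @return a [PopGrid-class] with role "estimate"
#' @export
disaggregate <- function(density, zones, census) {
  if (!identical(gridSpec(density), gridSpec(zones)))
    stop("density raster and zone map are on different grids")
  lab <- asValues(zones)
  k <- nZones(zones)
  if (!all(seq_len(k) %in% census$zone_id))
    stop("census must cover all zone labels")
  census <- census[match(seq_len(k), census$zone_id), ]
  d <- asValues(density)
  denom <- rowsum(as.vector(d), as.vector(lab))[, 1]
  degenerate <- denom == 0 & census$population > 0
  if (any(degenerate)) {
    warning(sum(degenerate), " zone(s) with zero predicted density but ",
            "positive population; falling back to uniform disaggregation")
    area <- tabulate(lab, nbins = k)
    for (z in which(degenerate)) d[lab == z] <- 1 / area[z]
    denom <- rowsum(as.vector(d), as.vector(lab))[, 1]
  }
  scale <- ifelse(census$population > 0, census$population / denom, 0)
  est <- d * matrix(scale[lab], nrow(d), ncol(d))
  new("PopGrid", values = est, grid = gridSpec(density), role = "estimate")
}
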