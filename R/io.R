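# File interchange: ESRI ASCII grid rasters, household/zone CSVs, YAML
# configuration.

#' Write a grid layer as an ESRI ASCII grid (.asc)
#'
#' Plain-text georeferenced raster: header (ncols, nrows, xllcorner,
#' yllcorner, cellsize, NODATA_value -1) followed by rows top-to-bottom.
#' Readable by any GIS.
#'
#' @param x a [GridLayer-class] (PopGrid, ZoneMap, StratumGrid,
#'   CovariateLayer) or a matrix with `grid` supplied
#' @param path output file path
#' @param grid a [GridSpec-class]; taken from `x` when it is a grid layer
#' @return `path`, invisibly
#' @export
writeAsciiGrid <- function(x, path, grid = NULL) {
  if (is(x, "GridLayer")) {
    grid <- gridSpec(x)
    m <- asValues(x)
  } else {
    if (is.null(grid)) stop("a GridSpec is required to write a bare matrix")
    m <- x
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %.10g", grid@originX),
    sprintf("yllcorner %.10g", grid@originY - nrow(m) * grid@cellSize),
    sprintf("cellsize %.10g", grid@cellSize),
    "NODATA_value -1"), con)
  utils::write.table(m, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid written by [writeAsciiGrid()]
#'
#' @param path file path
#' @param role role for the returned [PopGrid-class]
#' @return a [PopGrid-class]
#' @export
readAsciiGrid <- function(path, role = "truth") {
  lines <- readLines(path, n = 6)
  hdr <- lapply(strsplit(lines, "\\s+"), function(p) as.numeric(p[2]))
  names(hdr) <- vapply(strsplit(lines, "\\s+"), `[`, character(1), 1)
  m <- as.matrix(utils::read.table(path, skip = 6))
  dimnames(m) <- NULL
  grid <- gridSpecNew(hdr$nrows, hdr$ncols, cellSize = hdr$cellsize,
                      originX = hdr$xllcorner,
                      originY = hdr$yllcorner + hdr$nrows * hdr$cellsize)
  new("PopGrid", values = m, grid = grid, role = role)
}

#' Write / read a household table as CSV
#'
#' Columns `id,x,y,stratum,build_year,persons`.
#' @param households household table
#' @param path file path
#' @return `path` invisibly (write); the household table (read)
#' @export
writeHouseholds <- function(households, path) {
  checkHouseholds(households)
  utils::write.csv(households[, HH_COLS], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname writeHouseholds
#' @export
readHouseholds <- function(path) {
  hh <- utils::read.csv(path, stringsAsFactors = FALSE)
  hh$stratum <- factor(hh$stratum, levels = STRATA)
  checkHouseholds(hh)
  hh
}

#' Write / read a zone-level census table as CSV
#'
#' Columns `zone_id,population,area_cells,settled_cells`.
#' @param census ZoneTable data.frame
#' @param path file path
#' @export
writeZoneTable <- function(census, path) {
  utils::write.csv(census, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeZoneTable
#' @export
readZoneTable <- function(path) utils::read.csv(path)

# Serialisable list form of a SimulationConfig.
configToList <- function(config) {
  g <- config@grid
  list(
    grid = list(nRows = g@nRows, nCols = g@nCols, cellSize = g@cellSize,
                originX = g@originX, originY = g@originY),
    counts = as.list(config@counts),
    years = config@years,
    yearCounts = lapply(stats::setNames(STRATA, STRATA),
                        function(s) unname(config@yearCounts[, s])),
    meanHouseholdSize = config@meanHouseholdSize,
    sdLogHouseholdSize = config@sdLogHouseholdSize,
    cityCentre = config@cityCentre, cityRadius = config@cityRadius,
    nSlumPatches = config@nSlumPatches,
    slumPatchRadius = config@slumPatchRadius,
    densityDecay = config@densityDecay, maxPerCell = config@maxPerCell,
    yearJitter = config@yearJitter,
    nSmall = config@nSmall, nLarge = config@nLarge,
    covariates = config@covariates,
    numTrees = config@numTrees, mtry = config@mtry,
    pooledUndercount = config@pooledUndercount)
}

#' Write / read a simulation configuration as YAML
#'
#' @param config a [SimulationConfig-class]
#' @param path file path
#' @export
writeSimConfig <- function(config, path) {
  yaml::write_yaml(configToList(config), path)
  invisible(path)
}

#' @rdname writeSimConfig
#' @export
readSimConfig <- function(path) {
  lst <- yaml::read_yaml(path)
  grid <- gridSpecNew(lst$grid$nRows, lst$grid$nCols,
                      cellSize = lst$grid$cellSize,
                      originX = lst$grid$originX, originY = lst$grid$originY)
  counts <- unlist(lst$counts)[STRATA]
  yearCounts <- do.call(cbind, lapply(stats::setNames(STRATA, STRATA),
                                      function(s) lst$yearCounts[[s]]))
  covs <- lapply(lst$covariates, function(cv)
    covariateSpec(cv$name, cv$nativeFactor, cv$informativeness, cv$noiseSd,
                  cv$link))
  simConfig(grid = grid, counts = counts, years = unlist(lst$years),
            yearCounts = yearCounts,
            meanHouseholdSize = lst$meanHouseholdSize,
            sdLogHouseholdSize = lst$sdLogHouseholdSize,
            cityCentre = unlist(lst$cityCentre),
            cityRadius = lst$cityRadius, nSlumPatches = lst$nSlumPatches,
            slumPatchRadius = lst$slumPatchRadius,
            densityDecay = lst$densityDecay, maxPerCell = lst$maxPerCell,
            yearJitter = lst$yearJitter, nSmall = lst$nSmall,
            nLarge = lst$nLarge, covariates = covs,
            numTrees = lst$numTrees,
            mtry = if (is.null(lst$mtry)) NA_integer_ else lst$mtry,
            pooledUndercount = isTRUE(lst$pooledUndercount))
}
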