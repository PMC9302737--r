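# Orchestration: shared simulation phase, single-scenario runs, the full
# 32-scenario pipeline, and the reproducibility manifest.

logMsg <- function(..., logFile = NULL, quiet = FALSE) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), paste0(...))
  if (!quiet) message(msg)
  if (!is.null(logFile)) cat(msg, "\n", file = logFile, append = TRUE)
}

# Shared phase of every run: truth population, build years, truth raster,
# covariates, zone tilings. Keyed substreams make each product independent of
# the others, so any single scenario is reproducible in isolation.
buildTruth <- function(config, seed) {
  sim <- simulateHouseholds(config, seed)
  hh <- assignBuildYears(sim$households, config@yearCounts, config@years,
                         seed, jitter = config@yearJitter)
  truth <- rasterizeHouseholds(hh, config@grid)
  cov <- synthesizeCovariates(truth, config@covariates, seed)
  zones <- delineateZones(hh, config@grid, config@nSmall, config@nLarge)
  list(households = hh, strata = sim$strata, truth = truth, cov = cov,
       zones = zones)
}

# Model one census scenario: zonal features -> forest -> per-cell density ->
# pycnophylactic disaggregation. The forest substream is keyed by the full
# scenario id so scenarios do not perturb each other.
fitScenario <- function(scn, shared, config, seed) {
  zones <- shared$zones[[if (scn$aggregation == "small_zone") "small"
                         else "large"]]
  feats <- zonalFeatures(shared$cov, zones, scn$census)
  model <- trainDensityModel(feats, numTrees = config@numTrees,
                             mtry = config@mtry,
                             seed = derivedSeed(seed, paste0("rf_", scn$id)))
  dens <- predictDensity(model, shared$cov)
  list(estimate = disaggregate(dens, zones, scn$census), model = model)
}

#' Run a single census scenario end-to-end
#'
#' Rebuilds the shared truth population (deterministic under `seed`), builds
#' the requested degraded census, fits the density model, disaggregates, and
#' evaluates. Because every random substream is keyed by operation and
#' scenario, the result is byte-identical to the same scenario inside
#' [runAll()].
#'
#' @param config a [SimulationConfig-class]
#' @param seed master seed
#' @param year census reference year
#' @param inaccuracy one of "none", "low", "medium", "high"
#' @param aggregation "small" or "large"
#' @param evalConfig an [EvaluationConfig-class]
#' @return list with `estimate` (PopGrid), `metrics` (data.frame), `census`,
#'   `model`, `truth`, `strata`, `id`
#' @export
runScenario <- function(config, seed, year, inaccuracy = "none",
                        aggregation = c("small", "large"),
                        evalConfig = evaluationConfig()) {
  aggregation <- match.arg(aggregation)
  if (!inaccuracy %in% names(UNDERCOUNT_RATES))
    stop("unknown inaccuracy level '", inaccuracy, "' (use ",
         paste(names(UNDERCOUNT_RATES), collapse = "/"), ")")
  year <- as.integer(year)
  if (!year %in% config@years)
    stop("year ", year, " is not one of the configured census years")
  shared <- buildTruth(config, seed)
  scns <- scenarioMatrix(shared$households, shared$zones, seed,
                         years = year, levels = inaccuracy,
                         pooled = config@pooledUndercount)
  scn <- Filter(function(s)
    s$aggregation == paste0(if (aggregation == "small") "small" else "large",
                            "_zone"), scns)[[1]]
  fit <- fitScenario(scn, shared, config, seed)
  metrics <- stratifyAndReport(fit$estimate, shared$truth, shared$strata,
                               evalConfig, scenario = scn$id)
  list(estimate = fit$estimate, metrics = metrics, census = scn$census,
       model = fit$model, truth = shared$truth, strata = shared$strata,
       id = scn$id)
}

#' Run the full scenario matrix and write all artefacts
#'
#' Simulates the truth population once, degrades it into the year x
#' inaccuracy matrix, aggregates each degraded population at both zone
#' levels, models and evaluates every census (32 gridded datasets under the
#' defaults), and writes: the truth/strata/zone rasters, per-scenario census
#' CSVs and estimate rasters (ESRI ASCII grid), one consolidated metrics
#' CSV, a `run.log`, and a `manifest.json` with md5 checksums of every
#' artefact so re-runs can be verified byte-for-byte.
#'
#' @param config a [SimulationConfig-class] or path to a YAML config
#' @param seed master seed
#' @param outDir output directory (created if needed)
#' @param evalConfig an [EvaluationConfig-class]
#' @param quiet suppress progress messages
#' @param overwrite allow writing into a directory that already holds a run;
#'   by default a previous (possibly partial) run is detected and refused
#' @return the manifest, invisibly, with the metrics table attached as
#'   `$metrics`
#' @export
runAll <- function(config, seed, outDir, evalConfig = evaluationConfig(),
                   quiet = FALSE, overwrite = FALSE) {
  if (is.character(config)) config <- readSimConfig(config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (!overwrite && length(list.files(outDir, pattern = "\\.(asc|json)$")))
    stop("'", outDir, "' already contains run artefacts; ",
         "set overwrite = TRUE to replace them")
  logFile <- file.path(outDir, "run.log")
  cat("", file = logFile)
  logMsg("phase 1/4: simulating truth population", logFile = logFile,
         quiet = quiet)
  shared <- buildTruth(config, seed)
  writeAsciiGrid(shared$truth, file.path(outDir, "truth.asc"))
  writeAsciiGrid(shared$strata, file.path(outDir, "strata.asc"))
  writeAsciiGrid(shared$zones$small, file.path(outDir, "zones_small.asc"))
  writeAsciiGrid(shared$zones$large, file.path(outDir, "zones_large.asc"))
  writeHouseholds(shared$households, file.path(outDir, "households.csv"))

  logMsg("phase 2/4: building census scenario matrix", logFile = logFile,
         quiet = quiet)
  scns <- scenarioMatrix(shared$households, shared$zones, seed,
                         years = config@years,
                         pooled = config@pooledUndercount)

  logMsg("phase 3/4: modelling ", length(scns), " gridded datasets",
         logFile = logFile, quiet = quiet)
  allMetrics <- list()
  entries <- list()
  for (scn in scns) {
    fit <- fitScenario(scn, shared, config, seed)
    censusFile <- file.path(outDir, paste0("census_", scn$id, ".csv"))
    rasterFile <- file.path(outDir, paste0("pop_", scn$id, ".asc"))
    writeZoneTable(scn$census, censusFile)
    writeAsciiGrid(fit$estimate, rasterFile)
    jsonlite::write_json(
      list(scenario = scn$id, num_trees = fit$model@settings$numTrees,
           mtry = fit$model@settings$mtry, seed = fit$model@seed,
           covariates = fit$model@covariateNames,
           excluded_zones = fit$model@excludedZones,
           oob_r_squared = oobRsquared(fit$model)),
      file.path(outDir, paste0("pop_", scn$id, ".json")),
      auto_unbox = TRUE, pretty = TRUE, digits = NA)
    m <- stratifyAndReport(fit$estimate, shared$truth, shared$strata,
                           evalConfig, scenario = scn$id)
    allMetrics[[scn$id]] <- m
    entries[[scn$id]] <- list(
      id = scn$id, year = scn$year, inaccuracy = scn$inaccuracy,
      aggregation = scn$aggregation,
      census = basename(censusFile), raster = basename(rasterFile),
      raster_md5 = unname(tools::md5sum(rasterFile)),
      census_md5 = unname(tools::md5sum(censusFile)))
    logMsg("  modelled ", scn$id, logFile = logFile, quiet = quiet)
  }
  metrics <- do.call(rbind, allMetrics)
  rownames(metrics) <- NULL
  metricsFile <- file.path(outDir, "metrics.csv")
  utils::write.csv(metrics, metricsFile, row.names = FALSE, quote = FALSE)

  logMsg("phase 4/4: writing manifest", logFile = logFile, quiet = quiet)
  cfgFile <- file.path(outDir, "config.yaml")
  writeSimConfig(config, cfgFile)
  manifest <- list(
    package_version = as.character(utils::packageVersion("gridpopsim")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = as.integer(seed),
    config_md5 = unname(tools::md5sum(cfgFile)),
    truth_md5 = unname(tools::md5sum(file.path(outDir, "truth.asc"))),
    metrics_file = basename(metricsFile),
    metrics_md5 = unname(tools::md5sum(metricsFile)),
    n_scenarios = length(entries),
    scenarios = unname(entries))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest$metrics <- metrics
  invisible(manifest)
}
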