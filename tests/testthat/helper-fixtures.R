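# Shared fixtures (built once per test run) and naive loop oracles.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# A scaled-down study region: same structure as the Khomas-like default
# (city + slum blobs + sparse hinterland, 4 census years, nested zones,
# mixed-resolution covariates) at desk-test size.
tinyConfig <- function(...) {
  args <- list(
    grid = gridSpecNew(60, 60),
    counts = c(urban_slum = 600, urban_nonslum = 900, rural = 120),
    years = c(2001L, 2006L, 2011L, 2016L),
    yearCounts = cbind(urban_slum = c(200, 320, 480, 600),
                       urban_nonslum = c(600, 700, 820, 900),
                       rural = c(90, 100, 120, 120)),
    cityRadius = 14, nSlumPatches = 2L, slumPatchRadius = 5,
    nSmall = 40L, nLarge = 4L,
    covariates = list(covariateSpec("dens_fine", 1L, 0.9, 0.2),
                      covariateSpec("coarse_block", 3L, 0.7, 0.3)),
    numTrees = 100L)
  override <- list(...)
  args[names(override)] <- override
  do.call(simConfig, args)
}

tinyWorld <- function() fixture("tinyWorld", function() {
  cfg <- tinyConfig()
  shared <- gridpopsim:::buildTruth(cfg, 42L)
  shared$config <- cfg
  shared
})

# One modelled scenario on the tiny world, used by model/evaluation tests.
tinyScenario <- function() fixture("tinyScenario", function() {
  w <- tinyWorld()
  scn <- scenarioMatrix(w$households, w$zones, 42L, years = 2016L,
                        levels = "none")[[1]]
  fit <- gridpopsim:::fitScenario(scn, w, w$config, 42L)
  list(world = w, scn = scn, estimate = fit$estimate, model = fit$model)
})

# Hand-built household table: one row per (x, y, persons, stratum, year).
mkHouseholds <- function(x, y, persons = 1L, stratum = "rural",
                         build_year = 2016L) {
  n <- length(x)
  data.frame(id = seq_len(n), x = x, y = y,
             stratum = factor(rep_len(stratum, n), levels = STRATA),
             build_year = rep_len(as.integer(build_year), n),
             persons = rep_len(as.integer(persons), n))
}

# Naive loop implementations of the four metric kernels, kept deliberately
# element-by-element so they are independent of the vectorised kernels.
naivePopAdjRMSE <- function(est, truth) {
  n <- length(est); ss <- 0; st <- 0
  for (i in seq_len(n)) {
    ss <- ss + (est[i] - truth[i])^2
    st <- st + truth[i]
  }
  sqrt(ss / n) / (st / n)
}

naiveDensityRMSE <- function(est, truth, k) {
  n <- length(est); ss <- 0
  for (i in seq_len(n)) ss <- ss + (est[i] / k^2 - truth[i] / k^2)^2
  sqrt(ss / n)
}

naiveBias <- function(est, truth) {
  n <- length(est); s <- 0
  for (i in seq_len(n)) s <- s + (est[i] - truth[i])
  s / n
}

naiveRelativeBias <- function(est, truth) {
  n <- length(est); s <- 0; st <- 0
  for (i in seq_len(n)) {
    s <- s + (est[i] - truth[i])
    st <- st + truth[i]
  }
  (s / n) / (st / n)
}

naiveMisallocated <- function(est, truth) {
  bad <- 0; tot <- 0
  for (i in seq_along(est)) {
    tot <- tot + est[i]
    if (truth[i] == 0) bad <- bad + est[i]
  }
  100 * bad / tot
}

metricValue <- function(metrics, metric, stratum, k) {
  v <- metrics$value[metrics$metric == metric & metrics$stratum == stratum &
                       metrics$scale == k]
  stopifnot(length(v) == 1L)
  v
}
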