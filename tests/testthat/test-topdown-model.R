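test_that("zonal features average covariates and flag empty zones", {
  g <- gridSpecNew(2, 2, cellSize = 10, originX = 0, originY = 20)
  zones <- new("ZoneMap", grid = g, level = "small_zone",
               values = matrix(c(1L, 1L, 2L, 2L), 2, 2))
  lay <- new("CovariateLayer", grid = g, name = "c1", nativeFactor = 1L,
             informativeness = 1, noiseSd = 0, link = "identity",
             values = matrix(c(0, 2, 4, 6), 2, 2))
  st <- new("CovariateStack", layers = list(lay), grid = g)
  cen <- data.frame(zone_id = 1:2, population = c(8, 0),
                    area_cells = c(2L, 2L), settled_cells = c(2L, 0L))
  f <- zonalFeatures(st, zones, cen)
  expect_equal(f$c1, c(1, 5))
  expect_equal(f$density, c(4, 0))
  expect_equal(f$excluded, c(FALSE, TRUE))
  expect_equal(f$log_density, c(log(4), NA_real_))

  # constant covariate: every zone mean equals the constant
  lay2 <- new("CovariateLayer", grid = g, name = "c1", nativeFactor = 1L,
              informativeness = 1, noiseSd = 0, link = "identity",
              values = matrix(3.5, 2, 2))
  st2 <- new("CovariateStack", layers = list(lay2), grid = g)
  expect_equal(zonalFeatures(st2, zones, cen)$c1, c(3.5, 3.5))
})

test_that("a constant-density response is recovered exactly", {
  set.seed(1)
  feats <- data.frame(zone_id = 1:20, cov = rnorm(20),
                      density = 2.5, log_density = log(2.5),
                      excluded = FALSE)
  model <- trainDensityModel(feats, numTrees = 50L, seed = 9L)
  g <- gridSpecNew(3, 3, cellSize = 100)
  lay <- new("CovariateLayer", grid = g, name = "cov", nativeFactor = 1L,
             informativeness = 1, noiseSd = 0, link = "identity",
             values = matrix(rnorm(9), 3, 3))
  st <- new("CovariateStack", layers = list(lay), grid = g)
  dens <- predictDensity(model, st)
  expect_equal(gridValues(dens), matrix(2.5, 3, 3), tolerance = 1e-12)
})

test_that("zero-population zones are excluded from training", {
  set.seed(2)
  feats <- data.frame(zone_id = 1:10, cov = rnorm(10),
                      density = c(rep(2, 9), 0),
                      log_density = c(rep(log(2), 9), NA),
                      excluded = c(rep(FALSE, 9), TRUE))
  model <- trainDensityModel(feats, numTrees = 30L, seed = 1L)
  expect_equal(model@forest$num.samples, 9L)
  expect_identical(model@excludedZones, 10L)
  # fewer than 2 usable zones cannot be fit
  feats$excluded[1:9] <- TRUE
  expect_error(trainDensityModel(feats, numTrees = 30L), "at least 2")
})

test_that("a perfectly informative covariate explains zone densities", {
  # 50 zones whose log density is an exact monotone function of the feature
  set.seed(3)
  x <- sort(runif(50, 0, 4))
  feats <- data.frame(zone_id = 1:50, cov = x, density = exp(1.2 * x - 2),
                      log_density = 1.2 * x - 2, excluded = FALSE)
  model <- trainDensityModel(feats, numTrees = 300L, seed = 4L)
  expect_gte(oobRsquared(model), 0.9)
  # independent 1-nearest-neighbour oracle (leave-one-out) on the same
  # feature must also explain the response
  pred <- vapply(seq_along(x), function(i) {
    j <- which.min(abs(x[-i] - x[i]))
    feats$log_density[-i][j]
  }, numeric(1))
  r2nn <- 1 - sum((pred - feats$log_density)^2) /
    sum((feats$log_density - mean(feats$log_density))^2)
  expect_gte(r2nn, 0.9)
})

test_that("cell predictions are the exponential of the per-tree mean", {
  ts <- tinyScenario()
  model <- ts$model
  st <- ts$world$cov
  newdata <- as.data.frame(lapply(model@covariateNames, function(nm)
    as.vector(gridValues(st[[nm]]))))
  names(newdata) <- model@covariateNames
  # per-tree oracle: iterate trees independently and average by hand
  per <- predict(model@forest, data = newdata, predict.all = TRUE,
                 num.threads = 1)$predictions
  oracle <- exp(rowMeans(per))
  dens <- predictDensity(model, st)
  expect_equal(as.vector(gridValues(dens)), oracle, tolerance = 1e-12)
  expect_true(all(gridValues(dens) > 0))
  # missing covariate is an error
  sub <- new("CovariateStack", layers = st@layers[1], grid = st@grid)
  expect_error(predictDensity(model, sub), "missing")
})

test_that("disaggregation normalises densities to the census counts", {
  g <- gridSpecNew(2, 2, cellSize = 10, originX = 0, originY = 20)
  zones <- new("ZoneMap", grid = g, level = "small_zone",
               values = matrix(c(1L, 1L, 2L, 2L), 2, 2))
  mkDens <- function(v) new("PopGrid", grid = g, role = "density",
                            values = matrix(v, 2, 2))
  cen <- data.frame(zone_id = 1:2, population = c(8, 10),
                    area_cells = c(2L, 2L), settled_cells = c(2L, 2L))
  # zone 1 densities (1, 3) with population 8 -> (2, 6); zone 2 uniform
  est <- disaggregate(mkDens(c(1, 3, 5, 5)), zones, cen)
  expect_equal(as.vector(gridValues(est)), c(2, 6, 5, 5))
  # single-cell zones: the estimate is the census, covariates notwithstanding
  singles <- new("ZoneMap", grid = g, level = "small_zone",
                 values = matrix(1:4, 2, 2))
  cen4 <- data.frame(zone_id = 1:4, population = c(7, 1, 0, 3),
                     area_cells = 1L, settled_cells = 1L)
  est4 <- disaggregate(mkDens(runif(4, 0.1, 9)), singles, cen4)
  expect_equal(as.vector(gridValues(est4)), c(7, 1, 0, 3))
  # zero-population zone maps to all-zero cells
  cen0 <- data.frame(zone_id = 1:2, population = c(0, 10),
                     area_cells = c(2L, 2L), settled_cells = c(0L, 2L))
  est0 <- disaggregate(mkDens(c(1, 3, 5, 5)), zones, cen0)
  expect_equal(as.vector(gridValues(est0)), c(0, 0, 5, 5))
  # zero predicted density with positive population: uniform fallback
  expect_warning(
    estf <- disaggregate(mkDens(c(0, 0, 5, 5)), zones, cen),
    "uniform")
  expect_equal(as.vector(gridValues(estf)), c(4, 4, 5, 5))
})

test_that("per-zone estimate sums conserve the census (pycnophylaxis)", {
  ts <- tinyScenario()
  lab <- as.vector(gridValues(ts$world$zones$small))
  zoneSums <- rowsum(as.vector(gridValues(ts$estimate)), lab)[, 1]
  cen <- ts$scn$census
  relErr <- abs(zoneSums - cen$population) / pmax(cen$population, 1)
  expect_lt(max(relErr), 1e-9)
  expect_equal(sum(gridValues(ts$estimate)), sum(cen$population))
})

test_that("the modelling chain is deterministic under a fixed seed", {
  w <- tinyWorld()
  scn <- scenarioMatrix(w$households, w$zones, 42L, years = 2016L,
                        levels = "low")[[1]]
  a <- gridpopsim:::fitScenario(scn, w, w$config, 42L)
  b <- gridpopsim:::fitScenario(scn, w, w$config, 42L)
  expect_identical(gridValues(a$estimate), gridValues(b$estimate))
})
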