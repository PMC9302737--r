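test_that("metric kernels reproduce the worked examples", {
  expect_equal(popAdjustedRMSE(c(1, 3), c(2, 2)), 0.5)
  expect_equal(popBias(c(1, 3), c(2, 2)), 0)
  expect_equal(popBias(c(1, 1), c(2, 2)), -1)
  expect_equal(relativeBias(c(1, 1), c(2, 2)), -0.5)
  expect_equal(densityRMSE(c(2, 2), c(0, 4), k = 1), 2)
  expect_equal(densityRMSE(6, 10, k = 2), 1)  # one 2x2 block, hectare scale
  expect_equal(misallocatedFraction(c(3, 7), c(0, 10)), 30)
  # identical rasters: every error metric vanishes
  x <- matrix(runif(16, 0, 5), 4, 4)
  expect_equal(popAdjustedRMSE(x, x), 0)
  expect_equal(densityRMSE(x, x, k = 2), 0)
  expect_equal(popBias(x, x), 0)
  expect_equal(relativeBias(x, x), 0)
  expect_equal(misallocatedFraction(x + 1, x + 1), 0)
})

test_that("degenerate masks raise errors instead of silent values", {
  expect_error(popAdjustedRMSE(c(1, 2), c(0, 0)), "undefined")
  expect_error(relativeBias(c(1, 2), c(0, 0)), "undefined")
  expect_error(misallocatedFraction(c(0, 0), c(0, 1)), "undefined")
  expect_error(popBias(c(1), c(1), mask = FALSE), "no cells")
})

test_that("pop-adjusted RMSE is invariant to joint rescaling", {
  set.seed(21)
  truth <- runif(50, 1, 10)
  est <- truth + rnorm(50)
  base <- popAdjustedRMSE(est, truth)
  for (c in c(0.1, 3, 250))
    expect_equal(popAdjustedRMSE(c * est, c * truth), base)
})

test_that("kernels agree with naive loop oracles to 1e-12", {
  set.seed(33)
  for (rep in 1:20) {
    truth <- matrix(rpois(400, 2) * runif(400), 20, 20)
    est <- matrix(pmax(0, truth + rnorm(400)), 20, 20)
    e <- as.vector(est); t <- as.vector(truth)
    expect_equal(popAdjustedRMSE(est, truth), naivePopAdjRMSE(e, t),
                 tolerance = 1e-12)
    expect_equal(densityRMSE(est, truth, k = 3),
                 naiveDensityRMSE(e, t, 3), tolerance = 1e-12)
    expect_equal(popBias(est, truth), naiveBias(e, t), tolerance = 1e-12)
    expect_equal(relativeBias(est, truth), naiveRelativeBias(e, t),
                 tolerance = 1e-12)
    expect_equal(misallocatedFraction(est, truth), naiveMisallocated(e, t),
                 tolerance = 1e-12)
  }
})

test_that("misallocation is non-increasing under aggregation on divisible grids", {
  # theorem: an aggregated block is truth-unsettled iff all of its sub-cells
  # are, so the misallocated numerator can only shrink while the denominator
  # is conserved on grids the factor divides
  set.seed(44)
  n <- 36
  truth <- matrix(0, n, n)
  truth[sample(n * n, 80)] <- rpois(80, 5) + 1
  est <- matrix(runif(n * n, 0, 0.4), n, n)
  est[sample(n * n, 60)] <- runif(60, 1, 20)
  ks <- c(1, 2, 3, 4, 6, 9, 12)
  mis <- vapply(ks, function(k)
    misallocatedFraction(aggregateBlocks(est, k), aggregateBlocks(truth, k)),
    numeric(1))
  expect_true(all(diff(mis) <= 1e-12))
})

test_that("raising the inclusion threshold never increases n_cells", {
  ts <- tinyScenario()
  w <- ts$world
  thresholds <- c(0, 0.5, 1, 2, 5)
  for (k in c(1L, 3L)) {
    n <- vapply(thresholds, function(th) {
      m <- stratifyAndReport(ts$estimate, w$truth, w$strata,
                             evaluationConfig(scales = k, threshold = th))
      m$n_cells[m$metric == "bias" & m$stratum == "all"]
    }, numeric(1))
    expect_true(all(diff(n) <= 0))
  }
})

test_that("a perfect estimate scores zero at every scale", {
  w <- tinyWorld()
  perfect <- new("PopGrid", values = gridValues(w$truth),
                 grid = gridSpec(w$truth), role = "estimate")
  m <- stratifyAndReport(perfect, w$truth, w$strata,
                         evaluationConfig(scales = c(1L, 2L, 5L)))
  vals <- m$value[m$stratum == "all" & !is.na(m$value)]
  expect_true(all(abs(vals) < 1e-12))
})

test_that("stratified report covers all scales and satisfies the bias identity", {
  ts <- tinyScenario()
  w <- ts$world
  cfg <- evaluationConfig(scales = 1:10)
  m <- stratifyAndReport(ts$estimate, w$truth, w$strata, cfg,
                         scenario = "tiny")
  expect_setequal(unique(m$scale), 1:10)
  expect_equal(nrow(m), 10 * (length(STRATA) + 1) * 5)
  expect_equal(unique(m$scale_m), seq(100, 1000, by = 100))
  expect_true(all(m$n_cells[!is.na(m$value)] > 0))
  # weighted-mean identity: per-stratum biases recombine to the overall bias
  for (k in c(1, 2, 4)) {
    sub <- m[m$metric == "bias" & m$scale == k & !is.na(m$value), ]
    allRow <- sub[sub$stratum == "all", ]
    strat <- sub[sub$stratum != "all", ]
    expect_equal(sum(strat$value * strat$n_cells),
                 allRow$value * allRow$n_cells, tolerance = 1e-9)
  }
})

test_that("zero-truth blocks inherit the stratum of their map labels", {
  g <- gridSpecNew(2, 2, cellSize = 100)
  truth <- new("PopGrid", values = matrix(0, 2, 2), grid = g, role = "truth")
  est <- new("PopGrid", values = matrix(2, 2, 2), grid = g,
             role = "estimate")
  strata <- new("StratumGrid", values = matrix(c(1L, 1L, 1L, 3L), 2, 2),
                grid = g)
  m <- stratifyAndReport(est, truth, strata, evaluationConfig(scales = 2L))
  # the single aggregated block has no truth population; its stratum is the
  # plurality of cell labels (3 slum cells beat 1 rural)
  slumBias <- m$value[m$metric == "bias" & m$stratum == "urban_slum"]
  expect_equal(slumBias, 8)  # est 8, truth 0 in the one slum-labelled block
  expect_true(is.na(m$value[m$metric == "bias" & m$stratum == "rural"]))
})
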