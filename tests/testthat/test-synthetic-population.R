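test_that("generated stratum counts match the configuration exactly", {
  w <- tinyWorld()
  counts <- table(w$households$stratum)
  expect_equal(as.integer(counts[STRATA]),
               as.integer(w$config@counts[STRATA]))
  # most of the grid is unsettled hinterland
  expect_gt(mean(gridValues(w$truth) == 0), 0.6)
  # household stratum matches the stratum raster at its location
  idx <- cellIndex(gridSpec(w$truth), w$households$x, w$households$y)
  cellStrat <- gridValues(w$strata)[cbind(idx$row, idx$col)]
  expect_identical(cellStrat, as.integer(w$households$stratum))
})

test_that("all-zero counts give an empty table and an all-rural raster", {
  cfg <- simConfig(grid = gridSpecNew(60, 60),
                   counts = c(urban_slum = 0, urban_nonslum = 0, rural = 0),
                   yearCounts = matrix(0, 4, 3,
                                       dimnames = list(NULL, STRATA)),
                   cityRadius = 14, nSlumPatches = 2L, slumPatchRadius = 5,
                   nSmall = 40L, nLarge = 4L)
  sim <- simulateHouseholds(cfg, 1L)
  expect_equal(nrow(sim$households), 0L)
  expect_true(all(gridValues(sim$strata) == match("rural", STRATA)))
})

test_that("mean household size agrees with the configured distribution", {
  w <- tinyWorld()
  cfg <- w$config
  n <- nrow(w$households)
  # CLT oracle: the configured truncated lognormal has mean mu = 4 and
  # sd = mu * sqrt(exp(sigma^2) - 1) on the continuous scale
  sdSize <- cfg@meanHouseholdSize * sqrt(exp(cfg@sdLogHouseholdSize^2) - 1)
  se <- sdSize / sqrt(n)
  expect_lt(abs(mean(w$households$persons) - cfg@meanHouseholdSize), 3 * se)
  expect_true(all(w$households$persons >= 1))
})

test_that("the generator is bit-identical under a fixed seed", {
  cfg <- tinyConfig()
  a <- simulateHouseholds(cfg, 7L)
  b <- simulateHouseholds(cfg, 7L)
  expect_identical(a$households, b$households)
  expect_identical(gridValues(a$strata), gridValues(b$strata))
  c <- simulateHouseholds(cfg, 8L)
  expect_false(identical(a$households, c$households))
})

test_that("over-capacity configurations raise a capacity error", {
  cfg <- tinyConfig(maxPerCell = 0.001)
  expect_error(simulateHouseholds(cfg, 1L), "capacity")
})

test_that("build years reproduce cumulative year counts and grow outward", {
  w <- tinyWorld()
  cfg <- w$config
  hh <- w$households
  for (j in seq_along(cfg@years)) {
    for (s in STRATA) {
      got <- sum(hh$stratum == s & hh$build_year <= cfg@years[j])
      expect_equal(got, unname(cfg@yearCounts[j, s]),
                   info = sprintf("%s at %d", s, cfg@years[j]))
    }
  }
  # monotone growth: set at an earlier year is a subset (by id) of later sets
  ids <- lapply(cfg@years, function(y) hh$id[hh$build_year <= y])
  for (j in seq_len(length(ids) - 1))
    expect_true(all(ids[[j]] %in% ids[[j + 1]]))
  # outward growth: the oldest slum cohort sits nearer its centroid than
  # the newest, on average
  slum <- hh[hh$stratum == "urban_slum", ]
  d <- sqrt((slum$x - mean(slum$x))^2 + (slum$y - mean(slum$y))^2)
  expect_lt(mean(d[slum$build_year == min(cfg@years)]),
            mean(d[slum$build_year == max(cfg@years)]))
})

test_that("constant year counts put every household in the earliest year", {
  cfg <- tinyConfig()
  sim <- simulateHouseholds(cfg, 3L)
  counts <- table(sim$households$stratum)[STRATA]
  yc <- do.call(cbind, lapply(as.list(counts), function(n) rep(n, 4)))
  colnames(yc) <- STRATA
  hh <- assignBuildYears(sim$households, yc, cfg@years, 3L)
  expect_true(all(hh$build_year == min(cfg@years)))
})

test_that("non-monotone year counts are rejected", {
  cfg <- tinyConfig()
  sim <- simulateHouseholds(cfg, 3L)
  yc <- cfg@yearCounts
  yc[2, "urban_slum"] <- yc[1, "urban_slum"] - 10
  expect_error(assignBuildYears(sim$households, yc, cfg@years, 3L),
               "non-decreasing")
})

test_that("a perfect fine covariate equals log(1 + truth) cellwise", {
  w <- tinyWorld()
  st <- synthesizeCovariates(
    w$truth, list(covariateSpec("perfect", 1L, 1, 0)), 5L)
  expect_equal(gridValues(st[["perfect"]]), log1p(gridValues(w$truth)))
})

test_that("coarse covariates are exactly block-constant at their factor", {
  w <- tinyWorld()
  st <- synthesizeCovariates(
    w$truth, list(covariateSpec("coarse9", 9L, 0.8, 0.3)), 5L)
  v <- gridValues(st[["coarse9"]])
  nr <- nrow(v); nc <- ncol(v)
  for (bi in seq_len(ceiling(nr / 9))) for (bj in seq_len(ceiling(nc / 9))) {
    rows <- ((bi - 1) * 9 + 1):min(bi * 9, nr)
    cols <- ((bj - 1) * 9 + 1):min(bj * 9, nc)
    expect_equal(max(v[rows, cols]) - min(v[rows, cols]), 0)
  }
  # and the noise-free signal part equals independently computed block means
  noiseless <- synthesizeCovariates(
    w$truth, list(covariateSpec("sig9", 9L, 1, 0)), 5L)
  vs <- gridValues(noiseless[["sig9"]])
  z <- log1p(gridValues(w$truth))
  for (bi in c(1, 3, 7)) for (bj in c(2, 5, 7)) {
    rows <- ((bi - 1) * 9 + 1):min(bi * 9, nr)
    cols <- ((bj - 1) * 9 + 1):min(bj * 9, nc)
    expect_equal(vs[rows[1], cols[1]], mean(z[rows, cols]))
  }
})

test_that("uninformative covariates are uncorrelated with the truth", {
  g <- gridSpecNew(110, 110)
  set.seed(11)
  truth <- new("PopGrid", grid = g, role = "truth",
               values = matrix(rpois(110 * 110, 3), 110, 110))
  st <- synthesizeCovariates(
    truth, list(covariateSpec("noise", 1L, 0, 1)), 9L)
  expect_gte(length(gridValues(truth)), 1e4)
  r <- cor(as.vector(gridValues(st[["noise"]])),
           as.vector(gridValues(truth)))
  expect_lt(abs(r), 0.05)
})

test_that("zone tilings partition the grid, nest, and balance households", {
  w <- tinyWorld()
  cfg <- w$config
  small <- gridValues(w$zones$small)
  large <- gridValues(w$zones$large)
  expect_identical(sort(unique(as.vector(small))), seq_len(cfg@nSmall))
  expect_identical(sort(unique(as.vector(large))), seq_len(cfg@nLarge))
  # nesting: every small zone lies inside exactly one large zone
  for (z in seq_len(cfg@nSmall))
    expect_length(unique(large[small == z]), 1L)
  # balance: household counts per small zone within a factor 5
  idx <- cellIndex(gridSpec(w$truth), w$households$x, w$households$y)
  zoneOfHH <- small[cbind(idx$row, idx$col)]
  perZone <- tabulate(zoneOfHH, nbins = cfg@nSmall)
  perZone <- perZone[perZone > 0]
  expect_lte(max(perZone) / min(perZone), 5)
})

test_that("degenerate and infeasible zone requests are handled", {
  w <- tinyWorld()
  z1 <- delineateZones(w$households, gridSpec(w$truth), 1, 1)
  expect_true(all(gridValues(z1$small) == 1))
  expect_true(all(gridValues(z1$large) == 1))
  expect_error(
    delineateZones(w$households, gridSpec(w$truth), 10000, 10),
    "settled")
  expect_error(delineateZones(gridpopsim:::emptyHouseholds(),
                              gridSpec(w$truth), 2, 1),
               "at least one household")
})
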