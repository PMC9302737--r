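# Synthetic population generator: stratum geography, household placement,
# build-year assignment, synthetic covariates, and nested zone tilings.

#' Specify one synthetic covariate layer
#'
#' @param name layer name
#' @param nativeFactor native resolution as a multiple of the grid cell
#'   (9 emulates a ~900 m layer on a 100 m grid)
#' @param informativeness weight in `[0,1]` on the population-density signal;
#'   0 gives pure noise
#' @param noiseSd standard deviation of the per-native-block Gaussian noise
#' @param link "identity" or "negative" (sign-flipped signal, emulating
#'   distance-to-feature layers)
#' @return a covariate spec (plain list) accepted by [synthesizeCovariates()]
#' @export
covariateSpec <- function(name, nativeFactor = 1L, informativeness = 1,
                          noiseSd = 0, link = "identity") {
  stopifnot(is.character(name), length(name) == 1L, nativeFactor >= 1,
            informativeness >= 0, informativeness <= 1, noiseSd >= 0,
            link %in% c("identity", "negative"))
  list(name = name, nativeFactor = as.integer(nativeFactor),
       informativeness = informativeness, noiseSd = noiseSd, link = link)
}

# Default Khomas-like covariate suite: two fine distance-style layers, two
# ~300 m land-cover-style layers, and three ~900 m block layers (night-time
# lights / travel-time style) that produce the coarse-resolution "halo".
defaultCovariates <- function() {
  list(
    covariateSpec("dist_settlement", 1L, 0.70, 0.30, link = "negative"),
    covariateSpec("dist_roads",      1L, 0.40, 0.60, link = "negative"),
    covariateSpec("landcover_built", 3L, 0.70, 0.30),
    covariateSpec("landcover_veg",   3L, 0.40, 0.50, link = "negative"),
    covariateSpec("nightlights_a",   9L, 0.80, 0.20),
    covariateSpec("nightlights_b",   9L, 0.60, 0.40),
    covariateSpec("travel_time",     9L, 0.50, 0.50, link = "negative")
  )
}

#' Construct a simulation configuration
#'
#' All arguments default to the Khomas-like 2016 study conditions: 35,001
#' urban-slum, 57,843 urban-non-slum and 4,823 rural households on a 360 x 360
#' grid of 100 m cells, with cumulative counts for 2001/2006/2011 matching the
#' censal growth of the region, a city covering about 5% of the grid, 922
#' small and 10 large zones, and mixed-resolution covariates.
#'
#' @param grid a [GridSpec-class]
#' @param counts named household counts (urban_slum, urban_nonslum, rural)
#' @param years increasing census reference years
#' @param yearCounts cumulative per-stratum household counts per year
#'   (matrix, rows = years, columns = strata); must be non-decreasing and end
#'   at `counts`
#' @param meanHouseholdSize,sdLogHouseholdSize household size distribution
#'   (truncated lognormal; integerised without bias)
#' @param cityCentre,cityRadius city geometry (fractions of grid; cells)
#' @param nSlumPatches,slumPatchRadius,densityDecay slum blob geometry
#' @param maxPerCell capacity cap (mean households per cell per stratum)
#' @param yearJitter fringe-growth noise fraction
#' @param nSmall,nLarge number of small/large zones
#' @param covariates list of [covariateSpec()] entries
#' @param numTrees,mtry random-forest settings (mtry NA = ceiling(p/3))
#' @param pooledUndercount pool non-slum + rural households during undercount
#' @return a [SimulationConfig-class]
#' @export
simConfig <- function(grid = gridSpecNew(360, 360),
                      counts = c(urban_slum = 35001, urban_nonslum = 57843,
                                 rural = 4823),
                      years = c(2001L, 2006L, 2011L, 2016L),
                      yearCounts = NULL,
                      meanHouseholdSize = 4.0, sdLogHouseholdSize = 0.45,
                      cityCentre = c(0.5, 0.5), cityRadius = 45,
                      nSlumPatches = 4L, slumPatchRadius = 11,
                      densityDecay = 0.6, maxPerCell = 100,
                      yearJitter = 0.25,
                      nSmall = 922L, nLarge = 10L,
                      covariates = defaultCovariates(),
                      numTrees = 500L, mtry = NA_integer_,
                      pooledUndercount = FALSE) {
  if (is.null(yearCounts)) {
    if (identical(as.integer(years), c(2001L, 2006L, 2011L, 2016L)) &&
        identical(unname(counts[STRATA]), c(35001, 57843, 4823))) {
      yearCounts <- cbind(urban_slum    = c(13149, 18018, 28583, 35001),
                          urban_nonslum = c(41700, 49742, 55680, 57843),
                          rural         = c(3731, 4146, 4823, 4823))
    } else {
      # scale the default growth shape to the requested final counts
      shape <- cbind(urban_slum = c(.3757, .5148, .8166, 1),
                     urban_nonslum = c(.7209, .8599, .9626, 1),
                     rural = c(.7736, .8596, 1, 1))
      ny <- length(years)
      frac <- apply(shape, 2, function(s)
        stats::approx(seq(0, 1, length.out = 4), s,
                      seq(0, 1, length.out = max(ny, 2)))$y)[seq_len(ny), ,
                                                             drop = FALSE]
      yearCounts <- round(sweep(frac, 2, counts[STRATA], `*`))
      yearCounts[ny, ] <- counts[STRATA]
      yearCounts <- apply(yearCounts, 2, cummax)
      if (ny == 1L) yearCounts <- matrix(counts[STRATA], 1,
                                         dimnames = list(NULL, STRATA))
    }
    rownames(yearCounts) <- NULL
  }
  new("SimulationConfig", grid = grid, counts = counts[STRATA],
      years = as.integer(years), yearCounts = yearCounts,
      meanHouseholdSize = meanHouseholdSize,
      sdLogHouseholdSize = sdLogHouseholdSize,
      cityCentre = cityCentre, cityRadius = cityRadius,
      nSlumPatches = as.integer(nSlumPatches),
      slumPatchRadius = slumPatchRadius, densityDecay = densityDecay,
      maxPerCell = maxPerCell, yearJitter = yearJitter,
      nSmall = as.integer(nSmall), nLarge = as.integer(nLarge),
      covariates = covariates, numTrees = as.integer(numTrees),
      mtry = as.integer(mtry), pooledUndercount = pooledUndercount)
}

#' Simulate the "true" household population and its stratum geography
#'
#' Lays out a dense city (a disc covering roughly 5% of the grid under the
#' defaults) inside a largely unsettled hinterland; inside the city a small
#' number of seeded slum blobs form the urban-slum stratum and the remaining
#' urban cells the non-slum stratum. Households are placed by sampling cells
#' with density weights that decay away from the patch cores (slum), away
#' from the city centre (non-slum), or uniformly over the hinterland (rural),
#' then jittered uniformly within the cell. Household sizes are drawn from a
#' truncated lognormal and integerised without bias.
#'
#' @param config a [SimulationConfig-class]
#' @param seed master seed; the operation uses its own derived substream
#' @return list with `households` (data.frame id, x, y, stratum, build_year,
#'   persons — build_year initialised to the final year; see
#'   [assignBuildYears()]) and `strata` (a [StratumGrid-class])
#' @export
simulateHouseholds <- function(config, seed) {
  g <- config@grid
  nr <- g@nRows; nc <- g@nCols
  counts <- round(config@counts[STRATA])
  withSeed(derivedSeed(seed, "simulate_households"), {
    # cell-centre coordinates in cell units
    rows <- matrix(seq_len(nr) - 0.5, nr, nc)
    cols <- matrix(seq_len(nc) - 0.5, nr, nc, byrow = TRUE)
    ctr <- c(config@cityCentre[1] * nc, config@cityCentre[2] * nr)
    dCentre <- sqrt((cols - ctr[1])^2 + (rows - ctr[2])^2)
    urban <- dCentre <= config@cityRadius

    # slum blobs seeded well inside the city
    inner <- which(urban & dCentre <= 0.8 * config@cityRadius)
    if (length(inner) < config@nSlumPatches)
      stop("grid too small for the configured city geometry")
    seedCells <- sample(inner, config@nSlumPatches)
    sr <- (seedCells - 1L) %% nr + 0.5
    sc <- (seedCells - 1L) %/% nr + 0.5
    dSlum <- matrix(Inf, nr, nc)
    for (i in seq_len(config@nSlumPatches))
      dSlum <- pmin(dSlum, sqrt((cols - sc[i])^2 + (rows - sr[i])^2))
    slum <- urban & dSlum <= config@slumPatchRadius

    strat <- matrix(3L, nr, nc)
    strat[urban] <- 2L
    strat[slum] <- 1L
    strataGrid <- new("StratumGrid", values = strat, grid = g)

    if (sum(counts) == 0)
      return(list(households = emptyHouseholds(),
                  strata = new("StratumGrid", values = matrix(3L, nr, nc),
                               grid = g)))

    # per-stratum cell pools and density weights
    tau <- config@densityDecay
    pools <- list(
      urban_slum    = list(cells = which(strat == 1L),
                           w = exp(-dSlum[strat == 1L]^2 /
                                   (2 * (tau * config@slumPatchRadius)^2))),
      urban_nonslum = list(cells = which(strat == 2L),
                           w = exp(-dCentre[strat == 2L]^2 /
                                   (2 * (0.7 * config@cityRadius)^2))),
      rural         = list(cells = which(strat == 3L),
                           w = NULL))

    parts <- lapply(STRATA, function(s) {
      n <- counts[[s]]
      if (n == 0) return(NULL)
      pool <- pools[[s]]
      if (!length(pool$cells))
        stop("no cells available for stratum ", s)
      if (n > length(pool$cells) * config@maxPerCell)
        stop("capacity error: ", n, " ", s, " households exceed ",
             length(pool$cells), " cells at <= ", config@maxPerCell,
             " households/cell")
      cells <- if (is.null(pool$w))
        pool$cells[sample.int(length(pool$cells), n, replace = TRUE)]
      else
        pool$cells[sample.int(length(pool$cells), n, replace = TRUE,
                              prob = pool$w)]
      row <- (cells - 1L) %% nr + 1L
      col <- (cells - 1L) %/% nr + 1L
      s2 <- g@cellSize
      data.frame(
        x = g@originX + (col - 1 + stats::runif(n)) * s2,
        y = g@originY - (row - 1 + stats::runif(n)) * s2,
        stratum = factor(rep(s, n), levels = STRATA))
    })
    hh <- do.call(rbind, parts)
    n <- nrow(hh)
    # unbiased integerisation of a lognormal with the configured mean:
    # floor(X) + Bernoulli(frac(X)), truncated below at 1 person
    meanlog <- log(config@meanHouseholdSize) - config@sdLogHouseholdSize^2 / 2
    xs <- stats::rlnorm(n, meanlog, config@sdLogHouseholdSize)
    persons <- floor(xs) + stats::rbinom(n, 1L, xs - floor(xs))
    persons <- pmax(1L, as.integer(persons))
    hh <- data.frame(id = seq_len(n), x = hh$x, y = hh$y,
                     stratum = hh$stratum,
                     build_year = rep(max(config@years), n),
                     persons = persons)
    list(households = hh, strata = strataGrid)
  })
}

#' Assign build years emulating outward settlement growth
#'
#' For each stratum, the cumulative year counts determine how many households
#' existed by each reference year; the oldest cohorts are placed nearest the
#' stratum's settlement core (its household centroid) and newer cohorts
#' progressively toward the fringe, with Gaussian jitter so growth is
#' patterned but not perfectly concentric. Restricting to `build_year <= Y`
#' then reproduces the year-Y counts exactly.
#'
#' @param households household table from [simulateHouseholds()]
#' @param yearCounts matrix (rows = years, in increasing year order, rownames
#'   or `years` attribute optional — taken from `years`) of cumulative
#'   per-stratum counts; must be non-decreasing per stratum with the final
#'   row equal to the current stratum counts
#' @param years increasing integer years matching `yearCounts` rows
#' @param seed master seed (operation-keyed substream)
#' @param jitter sd of the placement noise as a fraction of the stratum's
#'   spatial spread
#' @return the household table with `build_year` filled in
#' @export
assignBuildYears <- function(households, yearCounts, years, seed,
                             jitter = 0.25) {
  checkHouseholds(households)
  years <- as.integer(years)
  if (is.unsorted(years, strictly = TRUE))
    stop("'years' must be strictly increasing")
  if (nrow(yearCounts) != length(years))
    stop("'yearCounts' must have one row per year")
  if (!all(STRATA %in% colnames(yearCounts)))
    stop("'yearCounts' must have stratum columns")
  ny <- length(years)
  for (s in STRATA) {
    n <- sum(households$stratum == s)
    yc <- yearCounts[, s]
    if (is.unsorted(yc))
      stop("year counts for ", s, " must be non-decreasing over time")
    if (yc[ny] != n)
      stop("final-year count for ", s, " (", yc[ny],
           ") must equal the current household count (", n, ")")
  }
  withSeed(derivedSeed(seed, "assign_build_years"), {
    out <- households
    for (s in STRATA) {
      ix <- which(households$stratum == s)
      if (!length(ix)) next
      cx <- mean(households$x[ix]); cy <- mean(households$y[ix])
      d <- sqrt((households$x[ix] - cx)^2 + (households$y[ix] - cy)^2)
      spread <- stats::sd(d)
      if (!is.finite(spread) || spread == 0) spread <- 1
      score <- d + stats::rnorm(length(ix), 0, jitter * spread)
      ord <- ix[order(score)]
      yc <- yearCounts[, s]
      cohort <- rep(years[ny], length(ix))
      cohort[seq_len(yc[1])] <- years[1]
      for (j in seq_len(ny - 1L) + 1L)
        if (yc[j] > yc[j - 1L])
          cohort[(yc[j - 1L] + 1L):yc[j]] <- years[j]
      out$build_year[ord] <- cohort
    }
    out
  })
}

#' Synthesise covariate layers from the true population raster
#'
#' Each layer is `informativeness * g(blockmean_f(log1p(density))) +
#' noiseSd * eps`, where the block mean and the standard-normal noise `eps`
#' are taken per `nativeFactor` x `nativeFactor` block (ragged edge blocks
#' use the cells present), so the layer is exactly constant within native
#' blocks. `g` is the identity or a sign flip. With `nativeFactor = 1`,
#' `informativeness = 1`, `noiseSd = 0` and the identity link, the layer
#' equals `log(1 + truth)` cellwise.
#'
#' @param truth the "true" [PopGrid-class] (persons per cell; cells are 1 ha)
#' @param specs non-empty list of [covariateSpec()] entries
#' @param seed master seed (operation-keyed substream)
#' @return a [CovariateStack-class]
#' @export
synthesizeCovariates <- function(truth, specs, seed) {
  if (!length(specs)) stop("'specs' must be non-empty")
  g <- gridSpec(truth)
  z <- log1p(asValues(truth))
  nr <- nrow(z); nc <- ncol(z)
  withSeed(derivedSeed(seed, "synthesize_covariates"), {
    layers <- lapply(specs, function(sp) {
      f <- sp$nativeFactor
      sig <- blockMeanExpand(z, f)
      if (sp$link == "negative") sig <- -sig
      nbr <- ceiling(nr / f); nbc <- ceiling(nc / f)
      eps <- matrix(stats::rnorm(nbr * nbc), nbr, nbc)
      vals <- sp$informativeness * sig +
        sp$noiseSd * expandBlocks(eps, f, nr, nc)
      new("CovariateLayer", values = vals, grid = g, name = sp$name,
          nativeFactor = f, informativeness = sp$informativeness,
          noiseSd = sp$noiseSd, link = sp$link)
    })
    new("CovariateStack", layers = layers, grid = g)
  })
}

# Morton (Z-order) code of 0-based (row, col); exact for dims < 2^15.
mortonCode <- function(row0, col0) {
  code <- numeric(length(row0))
  r <- row0; c <- col0
  for (b in 0:14) {
    code <- code + (c %% 2) * 2^(2 * b) + (r %% 2) * 2^(2 * b + 1)
    r <- r %/% 2
    c <- c %/% 2
  }
  code
}

# Greedy balanced cut of ordered weights into exactly n groups: close a group
# once its cumulative weight reaches its proportional target, but never leave
# fewer items than remaining groups.
balancedCut <- function(w, n) {
  m <- length(w)
  if (n > m) stop("cannot cut ", m, " items into ", n, " groups")
  total <- sum(w)
  cum <- cumsum(w)
  grp <- integer(m)
  zone <- 1L
  for (i in seq_len(m)) {
    grp[i] <- zone
    if (zone < n && (cum[i] >= zone * total / n || m - i <= n - zone))
      zone <- zone + 1L
  }
  grp
}

#' Delineate nested small and large zone tilings
#'
#' Settled cells (cells containing at least one household) are ordered along
#' a Morton (Z-order) space-filling curve and cut into `nSmall` runs of
#' near-equal household counts; every unsettled cell is then attached to its
#' nearest settled zone by a deterministic multi-source flood fill, so the
#' two tilings partition the grid. Large zones group runs of consecutive
#' small zones (again balanced on household counts), so small zones nest
#' exactly inside large zones.
#'
#' @param households household table (at least one household)
#' @param grid a [GridSpec-class]
#' @param nSmall,nLarge zone counts, `nSmall >= nLarge >= 1`
#' @param seed accepted for interface symmetry; the construction is
#'   deterministic given the households
#' @return list with `small` and `large` [ZoneMap-class] objects
#' @export
delineateZones <- function(households, grid, nSmall, nLarge, seed = 0L) {
  checkHouseholds(households)
  if (!nrow(households)) stop("need at least one household")
  nSmall <- as.integer(nSmall); nLarge <- as.integer(nLarge)
  if (nSmall < nLarge || nLarge < 1L) stop("need nSmall >= nLarge >= 1")
  nr <- grid@nRows; nc <- grid@nCols
  idx <- cellIndex(grid, households$x, households$y)
  if (anyNA(idx$row)) stop("household outside the grid extent")
  lin <- (idx$col - 1L) * nr + idx$row
  hhPerCell <- tabulate(lin, nbins = nr * nc)
  settled <- which(hhPerCell > 0L)
  if (nSmall > length(settled))
    stop("n_small = ", nSmall, " exceeds the ", length(settled),
         " settled cells")
  ord <- settled[order(mortonCode((settled - 1L) %% nr,
                                  (settled - 1L) %/% nr))]
  smallOf <- balancedCut(hhPerCell[ord], nSmall)

  lab <- matrix(0L, nr, nc)
  lab[ord] <- smallOf
  lab <- floodFillNearest(lab)

  zoneHH <- rowsum(hhPerCell[ord], smallOf)[, 1]
  largeOfSmall <- balancedCut(zoneHH, nLarge)
  largeLab <- matrix(largeOfSmall[lab], nr, nc)

  list(small = new("ZoneMap", values = lab, grid = grid,
                   level = "small_zone"),
       large = new("ZoneMap", values = largeLab, grid = grid,
                   level = "large_zone"))
}

# Deterministic multi-source flood fill: unlabelled cells (0) take the label
# of the first labelled 4-neighbour, scanning neighbours in a fixed order
# (up, left, right, down), iterated until the grid is covered.
floodFillNearest <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  while (any(lab == 0L)) {
    up    <- rbind(0L, lab[-nr, , drop = FALSE])
    down  <- rbind(lab[-1, , drop = FALSE], 0L)
    left  <- cbind(0L, lab[, -nc, drop = FALSE])
    right <- cbind(lab[, -1, drop = FALSE], 0L)
    cand <- up
    cand[cand == 0L] <- left[cand == 0L]
    cand[cand == 0L] <- right[cand == 0L]
    cand[cand == 0L] <- down[cand == 0L]
    fill <- lab == 0L & cand != 0L
    if (!any(fill)) stop("flood fill stalled (no labelled cells?)")
    lab[fill] <- cand[fill]
  }
  lab
}
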