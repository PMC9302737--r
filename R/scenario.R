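# Census degradation: outdatedness filtering, undercount removal, areal
# aggregation, and the 32-scenario matrix.

#' Restrict a population to households present by a reference year
#'
#' Emulates census outdatedness: retains exactly the households whose
#' `build_year` is at or before the reference year; ids are preserved, so the
#' household set at an earlier year is always a subset of the set at a later
#' year.
#'
#' @param households household table
#' @param referenceYear integer year
#' @return the filtered household table
#' @export
filterByYear <- function(households, referenceYear) {
  checkHouseholds(households)
  households[households$build_year <= referenceYear, , drop = FALSE]
}

#' Remove undercounted households at random within strata
#'
#' For each stratum with `N` households and undercount rate `r`, retains
#' exactly `floor((1 - r) * N)` households chosen uniformly at random; the
#' retained count never depends on the seed, only which households are
#' retained does, and removal carries no spatial pattern. With
#' `pooled = TRUE` the urban-non-slum and rural strata are pooled before
#' removal (retaining `floor((1 - r) * (N_nonslum + N_rural))` of the pool at
#' the shared non-slum/rural rate), mirroring censuses where those two groups
#' are undercounted jointly.
#'
#' @param households household table
#' @param rates named per-stratum undercount rates in `[0, 1]` (see
#'   [UNDERCOUNT_RATES])
#' @param seed master seed (operation-keyed substream)
#' @param pooled pool non-slum and rural households during removal
#' @return the degraded household table
#' @export
applyUndercount <- function(households, rates, seed, pooled = FALSE) {
  checkHouseholds(households)
  if (!all(STRATA %in% names(rates)))
    stop("'rates' must be named by the three strata")
  if (any(rates < 0 | rates > 1)) stop("rates must be in [0, 1]")
  withSeed(derivedSeed(seed, "apply_undercount"), {
    groups <- if (pooled) {
      if (rates[["urban_nonslum"]] != rates[["rural"]])
        stop("pooled removal requires equal non-slum and rural rates")
      list(list(ix = which(households$stratum == "urban_slum"),
                r = rates[["urban_slum"]]),
           list(ix = which(households$stratum %in%
                             c("urban_nonslum", "rural")),
                r = rates[["urban_nonslum"]]))
    } else {
      lapply(STRATA, function(s)
        list(ix = which(households$stratum == s), r = rates[[s]]))
    }
    keep <- unlist(lapply(groups, function(grp) {
      n <- length(grp$ix)
      nKeep <- floor((1 - grp$r) * n + 1e-9)  # guard binary-fraction rounding
      if (nKeep >= n) grp$ix else grp$ix[sample.int(n, nKeep)]
    }))
    out <- households[sort(keep), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Aggregate a household population into a zone-level census
#'
#' @param households household table
#' @param zones a [ZoneMap-class]
#' @return ZoneTable data.frame with columns `zone_id`, `population`
#'   (persons), `area_cells` (1 cell = 1 ha), `settled_cells`; one row per
#'   zone, populations summing to the table's person total
#' @export
makeCensus <- function(households, zones) {
  checkHouseholds(households)
  grid <- gridSpec(zones)
  lab <- asValues(zones)
  k <- nZones(zones)
  pop <- numeric(k)
  settled <- integer(k)
  if (nrow(households)) {
    idx <- cellIndex(grid, households$x, households$y)
    if (anyNA(idx$row)) stop("household outside the zoned grid")
    lin <- (idx$col - 1L) * grid@nRows + idx$row
    z <- lab[lin]
    agg <- rowsum(as.numeric(households$persons), z)
    pop[as.integer(rownames(agg))] <- agg[, 1]
    settledCells <- unique(lin)
    settled <- tabulate(lab[settledCells], nbins = k)
  }
  data.frame(zone_id = seq_len(k), population = pop,
             area_cells = tabulate(lab, nbins = k),
             settled_cells = settled)
}

#' Build the full census scenario matrix
#'
#' Crosses reference years with inaccuracy levels and aggregation levels
#' (4 x 4 x 2 = 32 under the defaults). Each (year, inaccuracy) pair shares
#' one degraded household table across its two aggregations, with the
#' undercount substream keyed by the pair only, so a census at one
#' aggregation level is byte-identical to its sibling's source population.
#'
#' @param households the "true" household table (build years assigned)
#' @param zones list with `small` and `large` [ZoneMap-class] (from
#'   [delineateZones()])
#' @param seed master seed
#' @param years reference years (default the four census years present)
#' @param levels inaccuracy levels (subset of names of [UNDERCOUNT_RATES])
#' @param pooled see [applyUndercount()]
#' @return list of scenarios, each a list with `year`, `inaccuracy`,
#'   `aggregation` ("small_zone"/"large_zone"), `id` (e.g.
#'   `y2011_imedium_asmall`), `census` (ZoneTable) and `households` (the
#'   degraded table)
#' @export
scenarioMatrix <- function(households, zones, seed,
                           years = sort(unique(households$build_year)),
                           levels = names(UNDERCOUNT_RATES),
                           pooled = FALSE) {
  checkHouseholds(households)
  if (!all(levels %in% names(UNDERCOUNT_RATES)))
    stop("unknown inaccuracy level: ",
         paste(setdiff(levels, names(UNDERCOUNT_RATES)), collapse = ", "))
  out <- list()
  for (year in years) {
    aged <- filterByYear(households, year)
    for (lev in levels) {
      degraded <- applyUndercount(
        aged, UNDERCOUNT_RATES[[lev]],
        derivedSeed(seed, paste0("scenario_", year, "_", lev)),
        pooled = pooled)
      for (agg in c("small", "large")) {
        zm <- zones[[agg]]
        out[[length(out) + 1L]] <- list(
          year = as.integer(year), inaccuracy = lev,
          aggregation = zm@level,
          id = sprintf("y%d_i%s_a%s", year, lev, agg),
          census = makeCensus(degraded, zm),
          households = degraded)
      }
    }
  }
  out
}
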