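# Cell-level accuracy statistics: population-adjusted RMSE, density RMSE,
# bias, relative bias, and misallocation to unsettled cells, across
# block-aggregated scales and strata.

#' Construct an evaluation configuration
#'
#' @param scales integer block factors k (default 1:10, i.e. 100 m to 1 km)
#' @param threshold inclusion threshold in persons (default 1): aggregated
#'   estimate cells below it are excluded from RMSE/bias statistics;
#'   misallocation never applies it
#' @param strata strata to report (an "all" row is always added)
#' @return an [EvaluationConfig-class]
#' @export
evaluationConfig <- function(scales = 1:10, threshold = 1, strata = STRATA) {
  new("EvaluationConfig", scales = as.integer(scales),
      threshold = as.numeric(threshold), strata = strata)
}

prepMask <- function(est, truth, mask) {
  e <- as.vector(asValues(est)); t <- as.vector(asValues(truth))
  if (length(e) != length(t)) stop("estimate and truth are not aligned")
  if (is.null(mask)) mask <- rep(TRUE, length(e))
  mask <- as.vector(mask)
  if (!any(mask)) stop("mask selects no cells")
  list(e = e[mask], t = t[mask], n = sum(mask))
}

#' Population-adjusted RMSE
#'
#' `sqrt(sum((est - truth)^2) / n) / (sum(truth) / n)` over the masked
#' cells: root-mean-square error expressed as a proportion of the mean true
#' cell population, comparable across cell sizes.
#'
#' @param est,truth aligned [PopGrid-class] objects or matrices
#' @param mask optional logical matrix/vector of cells to include
#' @return a single number (unitless proportion)
#' @export
popAdjustedRMSE <- function(est, truth, mask = NULL) {
  p <- prepMask(est, truth, mask)
  mt <- mean(p$t)
  if (mt == 0) stop("pop-adjusted RMSE undefined: mean truth is 0 over mask")
  sqrt(mean((p$e - p$t)^2)) / mt
}

#' RMSE of population density per hectare
#'
#' `sqrt(sum((Dhat - D)^2) / n)` where the densities are the cell counts
#' divided by `k^2` (a k-block of 100 m cells covers k^2 hectares). The
#' rasters must already be aggregated at factor k.
#'
#' @param est,truth aggregated rasters (counts per k-block)
#' @param k the block factor the rasters were aggregated at
#' @param mask optional logical mask
#' @return RMSE in persons per hectare
#' @export
densityRMSE <- function(est, truth, k = 1, mask = NULL) {
  p <- prepMask(est, truth, mask)
  sqrt(mean((p$e / k^2 - p$t / k^2)^2))
}

#' Mean cell-level bias
#'
#' `sum(est - truth) / n` over the masked cells; negative values mean the
#' estimate systematically under-counts.
#'
#' @param est,truth aligned rasters
#' @param mask optional logical mask
#' @return mean signed error, persons per cell
#' @export
popBias <- function(est, truth, mask = NULL) {
  p <- prepMask(est, truth, mask)
  mean(p$e - p$t)
}

#' Relative (population-adjusted) bias
#'
#' [popBias()] divided by the mean true cell population over the mask.
#'
#' @param est,truth aligned rasters
#' @param mask optional logical mask
#' @return unitless signed proportion
#' @export
relativeBias <- function(est, truth, mask = NULL) {
  p <- prepMask(est, truth, mask)
  mt <- mean(p$t)
  if (mt == 0) stop("relative bias undefined: mean truth is 0 over mask")
  mean(p$e - p$t) / mt
}

#' Percent of the estimated population misallocated to unsettled cells
#'
#' `100 * sum(est over cells with truth == 0) / sum(est)`. No inclusion
#' threshold is applied: near-zero estimates in unsettled cells are exactly
#' the phenomenon being measured.
#'
#' @param est,truth aligned rasters
#' @param mask optional logical restriction (e.g. one stratum's cells)
#' @return percent in `[0, 100]`
#' @export
misallocatedFraction <- function(est, truth, mask = NULL) {
  p <- prepMask(est, truth, mask)
  tot <- sum(p$e)
  if (tot == 0) stop("misallocated fraction undefined: estimate total is 0")
  100 * sum(p$e[p$t == 0]) / tot
}

# Stratum label of each aggregated cell: the stratum holding the plurality
# of the block's true population, ties broken slum > non-slum > rural; blocks
# with zero true population take the plurality of their cells' stratum-map
# labels (so coarse-covariate "halo" cells around the city evaluate as urban).
aggregateStrata <- function(truthM, stratM, k) {
  mass <- lapply(seq_along(STRATA), function(s)
    aggregateBlocks(truthM * (stratM == s), k))
  cnt <- lapply(seq_along(STRATA), function(s)
    aggregateBlocks((stratM == s) * 1, k))
  massMat <- do.call(cbind, lapply(mass, as.vector))
  cntMat <- do.call(cbind, lapply(cnt, as.vector))
  pick <- ifelse(rowSums(massMat) > 0,
                 max.col(massMat, ties.method = "first"),
                 max.col(cntMat, ties.method = "first"))
  matrix(pick, nrow(mass[[1]]), ncol(mass[[1]]))
}

#' Multi-scale, stratified accuracy report
#'
#' For every scale k, both rasters are block-aggregated (ragged edges
#' dropped), the inclusion mask is built from the aggregated estimate
#' (cells `>= threshold` persons), each aggregated cell is assigned the
#' stratum holding the plurality of its true population, and all five
#' metrics are computed per stratum plus an all-strata row. The
#' misallocated percentage ignores the inclusion mask. One row is emitted
#' for every (scale, stratum, metric) combination; where a metric is
#' undefined on its mask (e.g. no included cells) the value is NA with
#' `n_cells` 0.
#'
#' @param est estimate [PopGrid-class]
#' @param truth truth [PopGrid-class] on the same grid
#' @param strata a [StratumGrid-class]
#' @param cfg an [EvaluationConfig-class]
#' @param scenario scenario id recorded in the output
#' @return data.frame with columns `scenario`, `scale` (k), `scale_m`,
#'   `stratum`, `metric`, `value`, `n_cells`
#' @export
stratifyAndReport <- function(est, truth, strata, cfg = evaluationConfig(),
                              scenario = "scenario") {
  estM <- asValues(est); truthM <- asValues(truth)
  stratM <- asValues(strata)
  if (!all(dim(estM) == dim(truthM)) || !all(dim(estM) == dim(stratM)))
    stop("estimate, truth and strata are not aligned")
  cellM <- gridSpec(truth)@cellSize
  rows <- list()
  strataCodes <- match(cfg@strata, STRATA)
  for (k in cfg@scales) {
    E <- aggregateBlocks(estM, k)
    Tm <- aggregateBlocks(truthM, k)
    S <- aggregateStrata(truthM, stratM, k)
    incl <- E >= cfg@threshold
    groups <- c(list(all = matrix(TRUE, nrow(E), ncol(E))),
                stats::setNames(lapply(strataCodes, function(s) S == s),
                                STRATA[strataCodes]))
    for (gname in names(groups)) {
      gm <- groups[[gname]]
      mask <- gm & incl
      n <- sum(mask)
      val <- function(f, ...) if (n > 0) tryCatch(f(E, Tm, ...),
                                                  error = function(e) NA_real_)
                              else NA_real_
      add <- function(metric, value, nc) {
        rows[[length(rows) + 1L]] <<- data.frame(
          scenario = scenario, scale = k, scale_m = k * cellM,
          stratum = gname, metric = metric, value = value, n_cells = nc)
      }
      v <- val(popAdjustedRMSE, mask = mask)
      add("pop_adj_rmse", v, if (is.na(v)) 0L else n)
      v <- val(densityRMSE, k = k, mask = mask)
      add("density_rmse", v, if (is.na(v)) 0L else n)
      v <- val(popBias, mask = mask)
      add("bias", v, if (is.na(v)) 0L else n)
      v <- val(relativeBias, mask = mask)
      add("relative_bias", v, if (is.na(v)) 0L else n)
      # misallocation: no inclusion threshold
      nm <- sum(gm)
      vm <- if (nm > 0) tryCatch(misallocatedFraction(E, Tm, mask = gm),
                                 error = function(e) NA_real_)
            else NA_real_
      add("misallocated_pct", vm, if (is.na(vm)) 0L else nm)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
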