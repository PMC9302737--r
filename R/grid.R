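# Grid geometry, point-to-cell indexing, rasterisation and block aggregation.

#' Construct a GridSpec
#'
#' @param nRows,nCols grid dimensions
#' @param cellSize cell edge in metres (default 100 m, so 1 cell = 1 ha)
#' @param originX,originY coordinates of the top-left corner; by default the
#'   bottom-left corner sits at (0, 0)
#' @return a [GridSpec-class]
#' @examples
#' gridSpecNew(360, 360)
#' @export
gridSpecNew <- function(nRows, nCols, cellSize = 100,
                        originX = 0, originY = nRows * cellSize) {
  new("GridSpec", originX = as.numeric(originX), originY = as.numeric(originY),
      cellSize = as.numeric(cellSize), nRows = as.integer(nRows),
      nCols = as.integer(nCols))
}

#' Locate points on the grid
#'
#' Maps point coordinates to 1-based (row, col) cell indices under the
#' half-open convention: column c (0-based) covers
#' `[originX + c*s, originX + (c+1)*s)` and row r covers
#' `(originY - (r+1)*s, originY - r*s]` with row 0 at the top. A point exactly
#' on a shared vertical edge therefore belongs to the cell on its right, and a
#' point on a shared horizontal edge to the cell above it.
#'
#' @param grid a [GridSpec-class]
#' @param x,y point coordinates, metres
#' @return a list with integer vectors `row` and `col` (NA if outside)
#' @export
cellIndex <- function(grid, x, y) {
  s <- grid@cellSize
  # row r covers y in (originY-(r+1)s, originY-rs]  <=>  originY-y in [rs, (r+1)s)
  col0 <- floor((x - grid@originX) / s)
  row0 <- floor((grid@originY - y) / s)
  bad <- col0 < 0 | col0 >= grid@nCols | row0 < 0 | row0 >= grid@nRows
  col0[bad] <- NA_integer_
  row0[bad] <- NA_integer_
  list(row = as.integer(row0) + 1L, col = as.integer(col0) + 1L)
}

#' Rasterise a household table to per-cell person counts
#'
#' Sums the persons of all households whose point falls in each cell; the
#' raster total equals the table's person total.
#'
#' @param households a household table (columns id, x, y, stratum,
#'   build_year, persons)
#' @param grid a [GridSpec-class]
#' @return a [PopGrid-class] with role "truth"
#' @export
rasterizeHouseholds <- function(households, grid) {
  checkHouseholds(households)
  m <- matrix(0, grid@nRows, grid@nCols)
  if (nrow(households)) {
    idx <- cellIndex(grid, households$x, households$y)
    bad <- is.na(idx$row) | is.na(idx$col)
    if (any(bad))
      stop("household(s) outside the grid extent: id ",
           paste(utils::head(households$id[bad], 5), collapse = ", "))
    lin <- (idx$col - 1L) * grid@nRows + idx$row
    agg <- rowsum(as.numeric(households$persons), lin)
    m[as.integer(rownames(agg))] <- agg[, 1]
  }
  new("PopGrid", values = m, grid = grid, role = "truth")
}

#' Aggregate a raster by summing k x k blocks
#'
#' Partial (ragged) edge blocks are dropped, so the output is
#' `floor(nrow/k) x floor(ncol/k)`; `k = 1` is the identity.
#'
#' @param x a [PopGrid-class] or matrix
#' @param k integer block factor
#' @return a matrix of block sums (a PopGrid in, a PopGrid out)
#' @examples
#' aggregateBlocks(matrix(1:4, 2, 2, byrow = TRUE), 2)  # 10
#' @export
aggregateBlocks <- function(x, k) {
  m <- asValues(x)
  k <- as.integer(k)
  if (k < 1L) stop("'k' must be >= 1")
  if (k > nrow(m) || k > ncol(m))
    stop("block factor k = ", k, " exceeds the grid dimensions")
  if (k == 1L) out <- m
  else {
    nr <- nrow(m) %/% k
    nc <- ncol(m) %/% k
    m <- m[seq_len(nr * k), seq_len(nc * k), drop = FALSE]
    rs <- rowsum(m, rep(seq_len(nr), each = k))
    out <- t(rowsum(t(rs), rep(seq_len(nc), each = k)))
    dimnames(out) <- NULL
  }
  if (is(x, "PopGrid")) {
    g <- x@grid
    new("PopGrid", values = out, grid = gridSpecNew(
          nrow(out), ncol(out), cellSize = g@cellSize * k,
          originX = g@originX, originY = g@originY),
        role = x@role)
  } else out
}

# Block means at factor f, keeping ragged edge blocks (mean over the cells
# actually present), returned expanded back to the input dimensions so the
# result is exactly block-constant.
blockMeanExpand <- function(m, f) {
  if (f == 1L) return(m)
  ri <- ceiling(seq_len(nrow(m)) / f)
  ci <- ceiling(seq_len(ncol(m)) / f)
  sums <- rowsum(t(rowsum(m, ri)), ci)         # nBlockCols x nBlockRows
  cnt <- tcrossprod(tabulate(ci), tabulate(ri))
  means <- t(sums / cnt)                        # nBlockRows x nBlockCols
  expandBlocks(means, f, nrow(m), ncol(m))
}

# Expand a per-block matrix (ceiling(nr/f) x ceiling(nc/f)) to cell scale.
expandBlocks <- function(b, f, nr, nc) {
  ri <- ceiling(seq_len(nr) / f)
  ci <- ceiling(seq_len(nc) / f)
  matrix(b[cbind(rep(ri, nc), rep(ci, each = nr))], nr, nc)
}
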