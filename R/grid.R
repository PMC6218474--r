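#' Planar equal-area grid geometry
#'
#' Defines the shared geometry of all rasters in an analysis: a regular grid
#' of square cells of side \code{cellsize} km, anchored at the lower-left
#' corner (\code{xmin}, \code{ymin}). Row 1 is the top row (map convention);
#' cell centres are at half-cell offsets. Every cell counts equally in area
#' fractions, which matches working on an equal-area projection at 1-km
#' resolution.
#'
#' @param nrow,ncol number of rows and columns (positive integers).
#' @param cellsize cell side length in km.
#' @param xmin,ymin coordinates of the lower-left corner of the grid, km.
#' @return an object of class \code{hfp_grid}.
#' @export
hfp_grid <- function(nrow, ncol, cellsize = 1, xmin = 0, ymin = 0) {
  stopifnot(nrow >= 1, ncol >= 1, cellsize > 0)
  structure(
    list(nrow = as.integer(nrow), ncol = as.integer(ncol),
         cellsize = as.numeric(cellsize),
         xmin = as.numeric(xmin), ymin = as.numeric(ymin)),
    class = "hfp_grid")
}

#' @export
print.hfp_grid <- function(x, ...) {
  cat(sprintf("<hfp_grid> %d x %d cells, cellsize %g km, origin (%g, %g)\n",
              x$nrow, x$ncol, x$cellsize, x$xmin, x$ymin))
  invisible(x)
}

#' Single-band raster on an \code{hfp_grid}
#'
#' A thin wrapper around a numeric matrix (rows x cols, row 1 = top) plus the
#' grid geometry. \code{NA} encodes nodata.
#'
#' @param values numeric matrix with \code{grid$nrow} rows and
#'   \code{grid$ncol} columns, or a single number to fill the grid.
#' @param grid an \code{hfp_grid}.
#' @param epoch optional year label carried through to derived products.
#' @return an object of class \code{hfp_raster}.
#' @export
raster_layer <- function(values, grid, epoch = NULL) {
  stopifnot(inherits(grid, "hfp_grid"))
  if (length(values) == 1L)
    values <- matrix(as.numeric(values), grid$nrow, grid$ncol)
  if (!is.matrix(values) || nrow(values) != grid$nrow || ncol(values) != grid$ncol)
    stop("values must be a ", grid$nrow, " x ", grid$ncol, " matrix")
  structure(list(values = values, grid = grid, epoch = epoch),
            class = "hfp_raster")
}

#' @export
print.hfp_raster <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<hfp_raster> %d x %d%s; range [%g, %g], %d nodata cells\n",
              x$grid$nrow, x$grid$ncol,
              if (is.null(x$epoch)) "" else paste0(", epoch ", x$epoch),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA,
              sum(is.na(x$values))))
  invisible(x)
}

#' Test whether two grids (or rasters) share the same geometry
#' @param a,b \code{hfp_grid} or \code{hfp_raster} objects.
#' @return logical.
#' @export
same_grid <- function(a, b) {
  ga <- if (inherits(a, "hfp_raster")) a$grid else a
  gb <- if (inherits(b, "hfp_raster")) b$grid else b
  stopifnot(inherits(ga, "hfp_grid"), inherits(gb, "hfp_grid"))
  ga$nrow == gb$nrow && ga$ncol == gb$ncol &&
    isTRUE(all.equal(ga$cellsize, gb$cellsize)) &&
    isTRUE(all.equal(ga$xmin, gb$xmin)) && isTRUE(all.equal(ga$ymin, gb$ymin))
}

stop_if_grid_mismatch <- function(a, b, what = "rasters") {
  if (!same_grid(a, b)) {
    ga <- if (inherits(a, "hfp_raster")) a$grid else a
    gb <- if (inherits(b, "hfp_raster")) b$grid else b
    stop(sprintf(
      "grid mismatch between %s: %dx%d@%g(%g,%g) vs %dx%d@%g(%g,%g)", what,
      ga$nrow, ga$ncol, ga$cellsize, ga$xmin, ga$ymin,
      gb$nrow, gb$ncol, gb$cellsize, gb$xmin, gb$ymin))
  }
  invisible(TRUE)
}

#' Cell-centre coordinates of a grid
#'
#' @param grid an \code{hfp_grid}.
#' @return data.frame with columns \code{cell} (linear index, column-major as
#'   in R matrices), \code{row}, \code{col}, \code{x}, \code{y}.
#' @export
cell_centers <- function(grid) {
  stopifnot(inherits(grid, "hfp_grid"))
  row <- rep(seq_len(grid$nrow), times = grid$ncol)
  col <- rep(seq_len(grid$ncol), each = grid$nrow)
  cs <- grid$cellsize
  ymax <- grid$ymin + grid$nrow * cs
  data.frame(cell = seq_len(grid$nrow * grid$ncol), row = row, col = col,
             x = grid$xmin + (col - 0.5) * cs,
             y = ymax - (row - 0.5) * cs)
}
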