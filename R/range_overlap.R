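#' Point-in-polygon test (crossing number)
#'
#' Vectorized over points; the polygon is a single ring given as an unclosed
#' two-column vertex matrix. Points on an edge follow the usual half-open
#' crossing-number convention.
#'
#' @param px,py point coordinates.
#' @param poly two-column matrix of ring vertices.
#' @return logical vector.
#' @export
point_in_polygon <- function(px, py, poly) {
  stopifnot(is.matrix(poly), ncol(poly) >= 2, nrow(poly) >= 3)
  vx <- poly[, 1]; vy <- poly[, 2]
  nv <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- nv
  for (i in seq_len(nv)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Rasterize a range polygon onto the analysis grid
#'
#' A cell belongs to the range iff its centre lies inside the polygon
#' (centre-in-polygon rule; deterministic and oracle-checkable).
#'
#' @param poly two-column vertex matrix (unclosed ring).
#' @param grid an \code{hfp_grid}.
#' @param species_id identifier attached to the mask.
#' @return object of class \code{range_mask}: \code{species_id}, \code{cells}
#'   (column-major linear cell indices), \code{n} and the \code{grid}.
#' @export
rasterize_range <- function(poly, grid, species_id = NA_character_) {
  if (is.null(poly) || !is.matrix(poly) || nrow(poly) < 3)
    stop("empty or degenerate geometry for species ", species_id)
  cc <- cell_centers(grid)
  # bounding-box prefilter; the polygon test runs only on candidate cells
  cand <- cc$x >= min(poly[, 1]) & cc$x <= max(poly[, 1]) &
    cc$y >= min(poly[, 2]) & cc$y <= max(poly[, 2])
  cells <- cc$cell[cand][point_in_polygon(cc$x[cand], cc$y[cand], poly)]
  if (!length(cells))
    stop("no covered cell for species ", species_id)
  structure(list(species_id = species_id, cells = cells, n = length(cells),
                 grid = grid),
            class = "range_mask")
}

#' Construct a range mask directly from cell indices
#' @param cells column-major linear cell indices.
#' @param grid an \code{hfp_grid} (bounds check).
#' @param species_id identifier.
#' @return a \code{range_mask}.
#' @export
range_mask <- function(cells, grid, species_id = NA_character_) {
  cells <- as.integer(cells)
  if (!length(cells)) stop("no covered cell for species ", species_id)
  if (any(cells < 1L | cells > grid$nrow * grid$ncol))
    stop("cells outside grid bounds")
  structure(list(species_id = species_id, cells = cells, n = length(cells),
                 grid = grid),
            class = "range_mask")
}

mask_values <- function(mask, r) {
  stopifnot(inherits(mask, "range_mask"), inherits(r, "hfp_raster"))
  stop_if_grid_mismatch(mask$grid, r, "range mask and raster")
  r$values[mask$cells]
}

#' Cumulative HFP profile of a species range
#'
#' \code{E(v)}, v = 0..50: the fraction of (valid) range cells whose HFP value
#' is at most v. Nondecreasing with \code{E(50) = 1}.
#'
#' @param mask a \code{range_mask}.
#' @param hfp an integer HFP map.
#' @return named numeric vector of length 51 (names "0".."50").
#' @export
cumulative_profile <- function(mask, hfp) {
  v <- mask_values(mask, hfp)
  v <- v[!is.na(v)]
  if (!length(v)) stop("all-nodata mask for species ", mask$species_id)
  h <- tabulate(v + 1L, nbins = 51L)
  E <- cumsum(h) / length(v)
  names(E) <- 0:50
  E
}

#' Fraction of a range with HFP strictly above a threshold
#'
#' Thresholds are strict: \code{extent_above(..., t)} is the share of range
#' cells with HFP > t, i.e. HFP >= t + 1. Equals \code{1 - E(t)}.
#'
#' @param mask a \code{range_mask}.
#' @param hfp an integer HFP map.
#' @param t threshold in 0..49.
#' @return fraction in [0, 1].
#' @export
extent_above <- function(mask, hfp, t) {
  if (any(t < 0 | t > 49)) stop("threshold t out of range 0..49")
  v <- mask_values(mask, hfp)
  v <- v[!is.na(v)]
  if (!length(v)) stop("all-nodata mask for species ", mask$species_id)
  vapply(t, function(tt) mean(v > tt), numeric(1))
}

#' Change in above-threshold extent between epochs
#'
#' With the clamp on (the "no change" rule), the final-epoch value of each
#' cell is replaced by \code{max(initial, final)} before computing extents, so
#' per-cell decreases contribute nothing and the delta is nonnegative.
#'
#' @param mask a \code{range_mask}.
#' @param hfp93,hfp09 integer HFP maps on the same grid.
#' @param t thresholds in 0..49 (vector allowed).
#' @param clamp logical; apply the "no change" rule.
#' @return data.frame with \code{species_id}, \code{t}, \code{extent93},
#'   \code{extent09}, \code{delta}, \code{clamped}.
#' @export
extent_change <- function(mask, hfp93, hfp09, t = 0:49, clamp = TRUE) {
  stop_if_grid_mismatch(hfp93, hfp09, "epoch maps")
  if (any(t < 0 | t > 49)) stop("threshold t out of range 0..49")
  a <- mask_values(mask, hfp93)
  b <- mask_values(mask, hfp09)
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  if (!length(a)) stop("all-nodata mask for species ", mask$species_id)
  bf <- if (clamp) pmax(a, b) else b
  e93 <- vapply(t, function(tt) mean(a > tt), numeric(1))
  e09 <- vapply(t, function(tt) mean(bf > tt), numeric(1))
  data.frame(species_id = mask$species_id, t = t,
             extent93 = e93, extent09 = e09, delta = e09 - e93,
             clamped = clamp)
}

#' Mean HFP within a range
#' @param mask a \code{range_mask}.
#' @param hfp an HFP map.
#' @return arithmetic mean over valid range cells.
#' @export
mean_hfp <- function(mask, hfp) {
  v <- mask_values(mask, hfp)
  v <- v[!is.na(v)]
  if (!length(v)) stop("all-nodata mask for species ", mask$species_id)
  mean(v)
}

#' Per-species overlap table across a threshold grid
#'
#' Driver combining \code{\link{extent_change}} over a list of masks; the long
#' format feeds \code{\link{group_sweep}} and \code{\link{assemble_features}}.
#'
#' @param masks list of \code{range_mask} objects.
#' @param hfp93,hfp09 integer HFP maps.
#' @param t thresholds (default all, 0..49).
#' @param clamp logical; apply the "no change" rule.
#' @return long data.frame (species_id, t, extent93, extent09, delta, clamped).
#' @export
overlap_table <- function(masks, hfp93, hfp09, t = 0:49, clamp = TRUE) {
  do.call(rbind, lapply(masks, extent_change, hfp93 = hfp93, hfp09 = hfp09,
                        t = t, clamp = clamp))
}
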