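HFP_LAYERS <- c("built", "crop", "pasture", "popdensity", "nightlights",
                "railways", "roads", "waterways")
LANDUSE_LAYERS <- c("built", "crop", "pasture")

#' Exponential distance-decay scoring parameters
#'
#' Parameterizes the direct-buffer + exponential-decay scoring used for linear
#' infrastructure: a constant \code{direct_score} out to
#' \code{direct_radius_km}, then \code{indirect_score0 * exp(-k * (d -
#' direct_radius_km))} out to \code{max_dist_km}, zero beyond. The decay rate
#' \code{k} is derived so that the indirect score at \code{max_dist_km} equals
#' \code{zero_round_score} (a value that rounds to zero in the integer index).
#'
#' @param direct_radius_km radius of the full-score direct buffer, km.
#' @param direct_score score inside the direct buffer.
#' @param indirect_score0 indirect score at the edge of the direct buffer.
#' @param max_dist_km distance at which the influence is considered gone, km.
#' @param zero_round_score target indirect score at \code{max_dist_km};
#'   must round to 0 (i.e. be < 0.5).
#' @return object of class \code{decay_params} with the derived rate \code{k}
#'   (per km).
#' @export
decay_params <- function(direct_radius_km, direct_score, indirect_score0,
                         max_dist_km = 15, zero_round_score = 0.25) {
  stopifnot(direct_radius_km >= 0, direct_radius_km < max_dist_km,
            direct_score > 0, indirect_score0 >= 0,
            zero_round_score > 0, zero_round_score < 0.5)
  k <- if (indirect_score0 > 0)
    log(indirect_score0 / zero_round_score) / (max_dist_km - direct_radius_km)
  else Inf
  structure(list(direct_radius_km = direct_radius_km,
                 direct_score = direct_score,
                 indirect_score0 = indirect_score0,
                 max_dist_km = max_dist_km,
                 zero_round_score = zero_round_score, k = k),
            class = "decay_params")
}

#' Default decay parameters for the distance-scored layers
#'
#' Roads: score 8 inside the 500-m direct buffer, indirect influence starting
#' at 4 (half the direct score) decaying exponentially to ~0 at 15 km.
#' Waterways: score 4 at the bank (distance 0) decaying exponentially to ~0 at
#' 15 km. Only the endpoints are fixed by the index definition; the interior
#' shape is a documented package choice (see the methods vignette).
#'
#' @param layer \code{"roads"} or \code{"waterways"}.
#' @return a \code{decay_params} object.
#' @export
default_decay_params <- function(layer = c("roads", "waterways")) {
  layer <- match.arg(layer)
  switch(layer,
         roads = decay_params(0.5, 8, 4, 15),
         # direct_radius 0: the "direct" score applies only at distance 0
         # (bank-adjacent cells); decay starts immediately.
         waterways = decay_params(0, 4, 4, 15))
}

#' Score a distance raster (or vector) under a decay rule
#'
#' @param distance_km distances in km (>= 0; \code{NA} passes through).
#' @param params a \code{decay_params} object.
#' @return scores, same shape as \code{distance_km}.
#' @export
distance_decay_score <- function(distance_km, params) {
  stopifnot(inherits(params, "decay_params"))
  if (any(distance_km < 0, na.rm = TRUE)) stop("negative distance")
  d <- distance_km
  s <- numeric(length(d))
  s[] <- NA_real_
  direct <- !is.na(d) & d <= params$direct_radius_km
  beyond <- !is.na(d) & d > params$max_dist_km
  mid <- !is.na(d) & !direct & !beyond
  s[direct] <- params$direct_score
  s[beyond] <- 0
  if (params$indirect_score0 > 0) {
    s[mid] <- params$indirect_score0 *
      exp(-params$k * (d[mid] - params$direct_radius_km))
  } else s[mid] <- 0
  if (is.matrix(d)) dim(s) <- dim(d)
  s
}

#' Bundle eight raw pressure layers into a stack
#'
#' The eight layers of the cumulative index: \code{built}, \code{crop},
#' \code{pasture} (0/1 presence, mutually exclusive per cell),
#' \code{popdensity} (people per km^2), \code{nightlights} (radiance),
#' \code{railways}, \code{roads}, \code{waterways} (distance to the nearest
#' feature, km).
#'
#' @param layers named list of \code{hfp_raster} objects or matrices (one per
#'   layer name above).
#' @param grid an \code{hfp_grid}; required if any layer is a bare matrix.
#' @param epoch year label.
#' @return object of class \code{pressure_stack}.
#' @export
pressure_stack <- function(layers, grid = NULL, epoch = NULL) {
  if (!setequal(names(layers), HFP_LAYERS))
    stop("layers must be exactly: ", paste(HFP_LAYERS, collapse = ", "),
         "; missing: ",
         paste(setdiff(HFP_LAYERS, names(layers)), collapse = ", "))
  layers <- lapply(layers, function(l) {
    if (inherits(l, "hfp_raster")) return(l)
    if (is.null(grid)) stop("grid required when layers are bare matrices")
    raster_layer(l, grid)
  })
  g <- layers[[1]]$grid
  for (nm in names(layers)) stop_if_grid_mismatch(layers[[nm]], g, nm)
  if (any(layers$popdensity$values < 0, na.rm = TRUE))
    stop("negative density in popdensity layer")
  for (nm in LANDUSE_LAYERS) {
    v <- layers[[nm]]$values
    if (!all(v %in% c(0, 1) | is.na(v)))
      stop("non-boolean land-use input in layer ", nm)
  }
  lu <- layers$built$values + layers$crop$values + layers$pasture$values
  if (any(lu > 1, na.rm = TRUE))
    stop("built/crop/pasture must be mutually exclusive per cell")
  structure(list(grid = g, epoch = epoch, layers = layers),
            class = "pressure_stack")
}

#' @export
print.pressure_stack <- function(x, ...) {
  cat(sprintf("<pressure_stack> %d x %d, epoch %s, layers: %s\n",
              x$grid$nrow, x$grid$ncol,
              if (is.null(x$epoch)) "?" else x$epoch,
              paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

#' Standardize one raw pressure layer to the 0-10 score scale
#'
#' Scoring rules: built 10/0; cropland 7/0; pasture 4/0; population density 10
#' above 1,000 people per km^2 and \code{3.333 * log10(density + 1)} (capped at
#' 10) below; night lights scored 1-10 by deciles over lit (positive) cells
#' with unlit cells 0 and ties assigned the lower decile; railways 8 within the
#' 500-m direct buffer and 0 elsewhere (no indirect impact); roads and
#' waterways via \code{\link{distance_decay_score}}.
#'
#' @param layer_name one of the eight layer names.
#' @param raw an \code{hfp_raster} (or matrix with \code{grid}) of raw values;
#'   distance in km for railways/roads/waterways.
#' @param grid grid for a bare-matrix \code{raw}.
#' @param decay a \code{decay_params} for roads/waterways (defaults used if
#'   \code{NULL}).
#' @param rail_buffer_km direct buffer radius for railways.
#' @return an \code{hfp_raster} of scores in [0, 10], with the layer name in
#'   attribute \code{"layer"}.
#' @export
standardize_layer <- function(layer_name, raw, grid = NULL, decay = NULL,
                              rail_buffer_km = 0.5) {
  if (!layer_name %in% HFP_LAYERS)
    stop("unknown layer name: ", layer_name)
  if (!inherits(raw, "hfp_raster")) {
    if (is.null(grid)) stop("grid required when raw is a bare matrix")
    raw <- raster_layer(raw, grid)
  }
  v <- raw$values
  s <- switch(
    layer_name,
    built = ,
    crop = ,
    pasture = {
      if (!all(v %in% c(0, 1) | is.na(v)))
        stop("non-boolean land-use input in layer ", layer_name)
      v * c(built = 10, crop = 7, pasture = 4)[[layer_name]]
    },
    popdensity = {
      if (any(v < 0, na.rm = TRUE)) stop("negative density")
      pmin(10, 3.333 * log10(v + 1))
    },
    nightlights = nightlight_deciles(v),
    railways = ifelse(is.na(v), NA_real_, ifelse(v <= rail_buffer_km, 8, 0)),
    roads = distance_decay_score(v, decay %||% default_decay_params("roads")),
    waterways = distance_decay_score(
      v, decay %||% default_decay_params("waterways"))
  )
  dim(s) <- dim(v)
  out <- raster_layer(s, raw$grid, epoch = raw$epoch)
  attr(out, "layer") <- layer_name
  out
}

# Decile scores 1-10 over strictly positive cells; zeros (unlit) score 0.
# Ties share the lowest rank, hence the lower decile.
nightlight_deciles <- function(v) {
  s <- v * 0  # keeps NA pattern
  pos <- which(!is.na(v) & v > 0)
  if (length(pos)) {
    r <- rank(v[pos], ties.method = "min")
    s[pos] <- ceiling(10 * r / length(pos))
  }
  s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the cumulative human-footprint map from a pressure stack
#'
#' Standardizes all eight layers, sums the per-layer scores cell by cell,
#' rounds half-up to the nearest integer and clamps to [0, 50]. Any cell with
#' nodata in any layer is nodata in the result. With built, crop and pasture
#' mutually exclusive the maximum attainable value is 50
#' (10 + 10 + 10 + 8 + 8 + 4).
#'
#' @param stack a \code{pressure_stack}.
#' @param decay named list with optional \code{roads} and \code{waterways}
#'   \code{decay_params} overrides.
#' @return an integer-valued \code{hfp_raster} in [0, 50] carrying the stack's
#'   epoch.
#' @export
build_hfp <- function(stack, decay = list()) {
  stopifnot(inherits(stack, "pressure_stack"))
  total <- matrix(0, stack$grid$nrow, stack$grid$ncol)
  for (nm in HFP_LAYERS) {
    sl <- standardize_layer(nm, stack$layers[[nm]], decay = decay[[nm]])
    total <- total + sl$values  # NA propagates
  }
  v <- pmin(50, pmax(0, floor(total + 0.5)))  # round half-up, clamp
  dim(v) <- dim(total)
  raster_layer(v, stack$grid, epoch = stack$epoch)
}

#' Per-cell change between two epoch HFP maps
#'
#' Computes the per-cell delta (final minus initial) and the 51 x 51
#' transition-count matrix indexed by (initial value, final value). With
#' \code{clamp_decreases = TRUE} (the "no change" rule), cells whose value
#' decreased are treated as unchanged: their delta is 0 and they are counted
#' on the matrix diagonal.
#'
#' @param map93 initial-epoch integer HFP map.
#' @param map09 final-epoch integer HFP map on the same grid.
#' @param clamp_decreases logical; apply the "no change" rule.
#' @return object of class \code{hfp_change} with elements \code{delta}
#'   (\code{hfp_raster}), \code{matrix} (51 x 51 counts, rows = initial),
#'   \code{clamped} and \code{epochs}.
#' @export
hfp_change <- function(map93, map09, clamp_decreases = TRUE) {
  stopifnot(inherits(map93, "hfp_raster"), inherits(map09, "hfp_raster"))
  stop_if_grid_mismatch(map93, map09, "epoch maps")
  if (!is.null(map93$epoch) && !is.null(map09$epoch) &&
      identical(map93$epoch, map09$epoch))
    stop("epoch mismatch: both maps carry epoch ", map93$epoch)
  a <- map93$values
  b <- map09$values
  if (any(a != round(a), na.rm = TRUE) || any(b != round(b), na.rm = TRUE))
    stop("HFP maps must be integer-valued")
  ok <- !is.na(a) & !is.na(b)
  bf <- b
  if (clamp_decreases) bf[ok & b < a] <- a[ok & b < a]
  delta <- bf - a
  m <- table(factor(a[ok], levels = 0:50), factor(bf[ok], levels = 0:50))
  m <- matrix(as.integer(m), 51, 51,
              dimnames = list(initial = 0:50, final = 0:50))
  structure(list(delta = raster_layer(delta, map93$grid),
                 matrix = m, clamped = clamp_decreases,
                 epochs = c(map93$epoch, map09$epoch)),
            class = "hfp_change")
}
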