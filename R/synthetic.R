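#' Synthetic-world configuration
#'
#' Bundles every knob of the synthetic generator. Defaults describe the
#' stated world used throughout the tests: a 200 x 200 km equal-area
#' landscape with eight pressure layers at two epochs, ~30% of cells
#' intensifying between epochs (matching the observed share of land with
#' increased HFP), 300 species with blob-shaped ranges, a 2 x 3 realm
#' layout, and extinction-risk labels planted on the change in extent of
#' HFP >= \code{t_star} with a standardized logistic effect \code{beta} around
#' a 31% baseline high-risk rate (the observed global share).
#'
#' \code{t_star} uses the inclusive "HFP >= t_star" convention; the strict
#' threshold used everywhere internally is \code{t_star - 1} ("HFP > t").
#'
#' @param seed root seed; expanded into independent substream seeds for
#'   landscape, species and labels.
#' @param nrow,ncol,cellsize grid geometry (cells, km).
#' @param n_settlements,n_roads,n_rails,n_rivers landscape feature counts.
#' @param crop_frac,pasture_frac land-cover fractions of the grid.
#' @param intensify_frac target share of cells whose HFP increases 1993->2009
#'   (0 = identical epochs).
#' @param n_species number of species.
#' @param range_radius_meanlog,range_radius_sdlog log-normal distribution of
#'   range radii (km).
#' @param realm_layout realm blocks as c(block rows, block cols).
#' @param t_star planted inclusive HFP threshold (1..50).
#' @param beta effect size on the standardized delta-extent (logit scale).
#' @param base_high_risk baseline probability of a high-risk transition.
#' @param high_mix,low_mix composition of realized category pairs within the
#'   high-risk (threatened-retained : uplisted) and low-risk
#'   (LC-retained : downlisted) classes.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1, nrow = 200, ncol = 200, cellsize = 1,
                       n_settlements = 12, n_roads = 8, n_rails = 3,
                       n_rivers = 4, crop_frac = 0.15, pasture_frac = 0.20,
                       intensify_frac = 0.30, n_species = 300,
                       range_radius_meanlog = log(10),
                       range_radius_sdlog = 0.4,
                       realm_layout = c(2, 3),
                       t_star = 3, beta = 2, base_high_risk = 0.31,
                       high_mix = c(threatened_retained = 8, uplisted = 1),
                       low_mix = c(lc_retained = 60, downlisted = 1)) {
  stopifnot(n_species >= 10, t_star >= 1, t_star <= 50,
            intensify_frac >= 0, intensify_frac <= 1,
            base_high_risk > 0, base_high_risk < 1,
            crop_frac + pasture_frac < 1)
  seeds <- with_seed(as.integer(seed), sample.int(2^31 - 2, 3))
  structure(list(
    seed = as.integer(seed),
    seeds = c(landscape = seeds[1], species = seeds[2], labels = seeds[3]),
    nrow = nrow, ncol = ncol, cellsize = cellsize,
    n_settlements = n_settlements, n_roads = n_roads, n_rails = n_rails,
    n_rivers = n_rivers, crop_frac = crop_frac, pasture_frac = pasture_frac,
    intensify_frac = intensify_frac, n_species = n_species,
    range_radius_meanlog = range_radius_meanlog,
    range_radius_sdlog = range_radius_sdlog, realm_layout = realm_layout,
    t_star = t_star, strict_t = t_star - 1L, beta = beta,
    base_high_risk = base_high_risk, high_mix = high_mix, low_mix = low_mix),
    class = "sim_config")
}

# Spatially autocorrelated standard field: white noise put through repeated
# box smoothing with edge replication, then rescaled to mean 0 / sd 1.
smooth_field <- function(nr, nc, width = 11, passes = 2) {
  m <- matrix(stats::rnorm(nr * nc), nr, nc)
  half <- width %/% 2
  box1d <- function(x) {
    cs <- cumsum(c(0, x))
    n <- length(x)
    lo <- pmax(seq_len(n) - half, 1)
    hi <- pmin(seq_len(n) + half, n)
    (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  }
  for (i in seq_len(passes)) {
    m <- apply(m, 2, box1d)
    m <- t(apply(m, 1, box1d))
  }
  (m - mean(m)) / stats::sd(m)
}

# Random polyline across the grid: two edge endpoints plus jittered interior
# waypoints. Returns a (k+1) x 2 matrix of vertices (km coordinates).
random_polyline <- function(grid, n_way = 3, jitter_km = NULL, length_km = NULL) {
  W <- grid$ncol * grid$cellsize
  H <- grid$nrow * grid$cellsize
  if (is.null(jitter_km)) jitter_km <- 0.08 * min(W, H)
  if (is.null(length_km)) {
    edge_point <- function() {
      side <- sample.int(4, 1)
      switch(side,
             c(stats::runif(1, 0, W), 0), c(stats::runif(1, 0, W), H),
             c(0, stats::runif(1, 0, H)), c(W, stats::runif(1, 0, H)))
    }
    a <- edge_point(); b <- edge_point()
  } else {
    a <- c(stats::runif(1, 0, W), stats::runif(1, 0, H))
    ang <- stats::runif(1, 0, 2 * pi)
    b <- a + length_km * c(cos(ang), sin(ang))
  }
  s <- seq(0, 1, length.out = n_way + 2)
  pts <- cbind(a[1] + s * (b[1] - a[1]), a[2] + s * (b[2] - a[2]))
  mid <- 2:(n_way + 1)
  pts[mid, 1] <- pts[mid, 1] + stats::rnorm(n_way, 0, jitter_km)
  pts[mid, 2] <- pts[mid, 2] + stats::rnorm(n_way, 0, jitter_km)
  pts
}

# Distance (km) from every cell centre to the nearest of a list of polylines.
polyline_distance <- function(polylines, grid) {
  cc <- cell_centers(grid)
  d2 <- rep(Inf, nrow(cc))
  for (pl in polylines) {
    for (i in seq_len(nrow(pl) - 1)) {
      ax <- pl[i, 1]; ay <- pl[i, 2]
      bx <- pl[i + 1, 1]; by <- pl[i + 1, 2]
      vx <- bx - ax; vy <- by - ay
      len2 <- vx * vx + vy * vy
      tt <- if (len2 == 0) 0 else
        pmin(1, pmax(0, ((cc$x - ax) * vx + (cc$y - ay) * vy) / len2))
      dx <- cc$x - (ax + tt * vx)
      dy <- cc$y - (ay + tt * vy)
      d2 <- pmin(d2, dx * dx + dy * dy)
    }
  }
  m <- matrix(NA_real_, grid$nrow, grid$ncol)
  m[cbind(cc$row, cc$col)] <- sqrt(d2)
  m
}

point_distance <- function(px, py, grid) {
  cc <- cell_centers(grid)
  d2 <- rep(Inf, nrow(cc))
  for (j in seq_along(px)) {
    dx <- cc$x - px[j]; dy <- cc$y - py[j]
    d2 <- pmin(d2, dx * dx + dy * dy)
  }
  m <- matrix(NA_real_, grid$nrow, grid$ncol)
  m[cbind(cc$row, cc$col)] <- sqrt(d2)
  m
}

#' Generate the two-epoch synthetic pressure landscape
#'
#' Epoch 1: land-use patches from thresholded smoothed noise (crop and
#' pasture bands, mutually exclusive), settlement-driven built / population
#' density / night lights, and random polylines for roads, railways and
#' navigable waterways (stored as distance-to-feature rasters). Epoch 2
#' intensifies a spatially coherent subset of cells of expected share
#' \code{intensify_frac} (land-use succession and population growth) and adds
#' a few short road spurs. With \code{intensify_frac = 0} the epochs are
#' identical.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{stack93} and \code{stack09}
#'   (\code{\link{pressure_stack}} objects) and the underlying
#'   \code{polylines}.
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  grid <- hfp_grid(config$nrow, config$ncol, config$cellsize)
  with_seed(config$seeds[["landscape"]], {
    nr <- grid$nrow; nc <- grid$ncol
    W <- nc * grid$cellsize; H <- nr * grid$cellsize
    if (min(W, H) < 20 && config$n_roads + config$n_rails + config$n_rivers > 0)
      stop("grid too small for requested line features")

    u <- smooth_field(nr, nc)
    q_crop <- stats::quantile(u, 1 - config$crop_frac)
    q_past <- stats::quantile(u, 1 - config$crop_frac - config$pasture_frac)
    crop <- (u >= q_crop) * 1
    pasture <- (u >= q_past & u < q_crop) * 1

    sx <- stats::runif(config$n_settlements, 0.05 * W, 0.95 * W)
    sy <- stats::runif(config$n_settlements, 0.05 * H, 0.95 * H)
    amp <- stats::rlnorm(config$n_settlements, log(3000), 0.5)
    d_set <- point_distance(sx, sy, grid)
    built <- (d_set <= 1.5) * 1
    crop[built == 1] <- 0
    pasture[built == 1] <- 0

    cc <- cell_centers(grid)
    dens <- matrix(0, nr, nc)
    for (j in seq_len(config$n_settlements)) {
      dx <- cc$x - sx[j]; dy <- cc$y - sy[j]
      dj <- matrix(0, nr, nc)
      dj[cbind(cc$row, cc$col)] <- amp[j] * exp(-(dx^2 + dy^2) / (2 * 3^2))
      dens <- dens + dj
    }
    dens <- dens + stats::runif(nr * nc, 0, 3) * (crop + pasture + built > 0)

    lights_noise <- exp(matrix(stats::rnorm(nr * nc, 0, 0.3), nr, nc))
    lights <- ifelse(dens > 20, dens * lights_noise, 0)

    roads <- lapply(seq_len(config$n_roads), function(i) random_polyline(grid))
    rails <- lapply(seq_len(config$n_rails), function(i) random_polyline(grid))
    rivers <- lapply(seq_len(config$n_rivers), function(i)
      random_polyline(grid, n_way = 4))
    d_road <- polyline_distance(roads, grid)
    d_rail <- polyline_distance(rails, grid)
    d_river <- polyline_distance(rivers, grid)

    layers93 <- list(built = built, crop = crop, pasture = pasture,
                     popdensity = dens, nightlights = lights,
                     railways = d_rail, roads = d_road, waterways = d_river)
    stack93 <- pressure_stack(layers93, grid, epoch = 1993)

    if (config$intensify_frac == 0) {
      stack09 <- pressure_stack(layers93, grid, epoch = 2009)
      return(list(stack93 = stack93, stack09 = stack09,
                  polylines = list(roads = roads, rails = rails,
                                   rivers = rivers)))
    }

    z <- smooth_field(nr, nc)
    S <- z >= stats::quantile(z, 1 - config$intensify_frac)
    crop09 <- crop; pasture09 <- pasture
    # land-use succession in intensifying cells: bare -> pasture -> crop
    bare <- S & built == 0 & crop == 0 & pasture == 0
    pasture09[bare] <- 1
    upgraded <- S & pasture == 1
    pasture09[upgraded] <- 0
    crop09[upgraded] <- 1
    dens09 <- dens
    dens09[S] <- pmax(dens[S] * 3, 30)
    lights09 <- ifelse(dens09 > 20, dens09 * lights_noise, 0)

    n_new <- max(1L, round(0.25 * config$n_roads))
    new_roads <- lapply(seq_len(n_new), function(i)
      random_polyline(grid, n_way = 1, length_km = 0.15 * min(W, H)))
    d_road09 <- pmin(d_road, polyline_distance(new_roads, grid))

    layers09 <- list(built = built, crop = crop09, pasture = pasture09,
                     popdensity = dens09, nightlights = lights09,
                     railways = d_rail, roads = d_road09, waterways = d_river)
    list(stack93 = stack93,
         stack09 = pressure_stack(layers09, grid, epoch = 2009),
         polylines = list(roads = roads, rails = rails, rivers = rivers,
                          new_roads = new_roads))
  })
}

blob_polygon <- function(cx, cy, r0, n_vert = 24) {
  phi <- stats::runif(3, 0, 2 * pi)
  a <- c(stats::runif(1, 0.1, 0.3), stats::runif(1, 0.05, 0.2),
         stats::runif(1, 0.02, 0.1))
  th <- seq(0, 2 * pi, length.out = n_vert + 1)[-(n_vert + 1)]
  r <- r0 * (1 + a[1] * sin(2 * th + phi[1]) + a[2] * sin(3 * th + phi[2]) +
               a[3] * sin(5 * th + phi[3]))
  r <- pmax(r, 0.2 * r0)
  cbind(cx + r * cos(th), cy + r * sin(th))
}

#' Generate synthetic species: ranges, covariates and realm rasters
#'
#' Ranges are blob-shaped polygons (log-normal radii, sinusoidal boundary
#' perturbation) rasterized with the centre-in-polygon rule. Covariates
#' mirror the global model's predictor set (life-history, pressure and
#' environmental variables) and are drawn from documented distributions that
#' are independent of the landscape. The realm raster partitions the grid
#' into \code{realm_layout} rectangular blocks (codes 1..6); a two-biome
#' raster built from smoothed noise defines biome-realms (realm * 10 +
#' biome).
#'
#' @param config a \code{\link{sim_config}}.
#' @param grid the analysis grid (defaults to the config's).
#' @return list: \code{polygons} (named list), \code{masks}
#'   (\code{range_mask} list), \code{covariates} (data.frame),
#'   \code{realm_raster}, \code{biome_realm_raster}.
#' @export
generate_species <- function(config, grid = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(grid)) grid <- hfp_grid(config$nrow, config$ncol, config$cellsize)
  with_seed(config$seeds[["species"]], {
    W <- grid$ncol * grid$cellsize; H <- grid$nrow * grid$cellsize
    n <- config$n_species
    ids <- sprintf("sp%03d", seq_len(n))
    polygons <- vector("list", n); names(polygons) <- ids
    masks <- vector("list", n)
    for (i in seq_len(n)) {
      ok <- FALSE
      for (try in 1:10) {
        cx <- stats::runif(1, 0.08 * W, 0.92 * W)
        cy <- stats::runif(1, 0.08 * H, 0.92 * H)
        r0 <- min(stats::rlnorm(1, config$range_radius_meanlog,
                                config$range_radius_sdlog),
                  0.25 * min(W, H))
        r0 <- max(r0, 1.5 * grid$cellsize)
        poly <- blob_polygon(cx, cy, r0)
        m <- tryCatch(rasterize_range(poly, grid, ids[i]),
                      error = function(e) NULL)
        if (!is.null(m)) { ok <- TRUE; break }
      }
      if (!ok) stop("range generation failure for ", ids[i])
      polygons[[i]] <- poly
      masks[[i]] <- m
    }

    body_mass <- stats::rlnorm(n, log(5000), 1.5)
    covariates <- data.frame(
      species_id = ids,
      popdensity = stats::rlnorm(n, log(25), 1),
      pop_growth = stats::rnorm(n, 0.15, 0.1),
      travel_time = stats::rlnorm(n, log(300), 0.8),
      taxon_order = sample(c("Rodentia", "Chiroptera", "Primates",
                             "Carnivora", "Artiodactyla", "Eulipotyphla",
                             "Lagomorpha", "Didelphimorphia"), n,
                           replace = TRUE),
      gestation_length = pmax(10, 30 + 15 * log10(body_mass) +
                                stats::rnorm(n, 0, 10)),
      weaning_age = pmax(5, 20 + 10 * log10(body_mass) +
                           stats::rnorm(n, 0, 8)),
      body_mass = body_mass,
      diet = sample(c("carnivore", "omnivore", "herbivore"), n,
                    replace = TRUE),
      habitat_class = sample(c("forest", "grassland", "savanna", "shrubland",
                               "desert", "generalist"), n, replace = TRUE),
      ndvi = stats::runif(n, 0.2, 0.9),
      tree_cover = stats::runif(n, 0, 100),
      habitat_prevalence = stats::runif(n, 0.1, 1))

    br <- config$realm_layout[1]; bc <- config$realm_layout[2]
    row_block <- ceiling(seq_len(grid$nrow) / (grid$nrow / br))
    col_block <- ceiling(seq_len(grid$ncol) / (grid$ncol / bc))
    realm <- outer(row_block, col_block,
                   function(r, c) (r - 1L) * bc + c)
    biome <- (smooth_field(grid$nrow, grid$ncol) >= 0) + 1L
    list(polygons = polygons, masks = masks, covariates = covariates,
         realm_raster = raster_layer(realm, grid),
         biome_realm_raster = raster_layer(realm * 10L + biome, grid))
  })
}

#' Plant category histories driven by change in high-HFP extent
#'
#' For each species the clamped change in extent of HFP >= \code{t_star}
#' (strict threshold \code{t_star - 1}) is standardized across species; the
#' probability of a high-risk transition is
#' \code{plogis(qlogis(base_high_risk) + beta * z)}. Labels are drawn and
#' realized as Red List category pairs whose composition follows the
#' configured mixes (threatened-retained vs uplisted within high-risk;
#' LC-retained vs downlisted within low-risk), so that re-classifying the
#' pairs reproduces the drawn labels exactly.
#'
#' @param config a \code{\link{sim_config}}.
#' @param masks list of \code{range_mask}.
#' @param hfp93,hfp09 integer HFP maps for the two epochs.
#' @return list: \code{histories} (species_id, cat_start, cat_end),
#'   \code{labels} (species_id, risk_class, uplist_class), \code{truth}
#'   (per-species delta/z/p/label plus the planted parameters as
#'   attributes).
#' @export
generate_transitions <- function(config, masks, hfp93, hfp09) {
  stopifnot(inherits(config, "sim_config"))
  t <- config$strict_t
  ov <- overlap_table(masks, hfp93, hfp09, t = t, clamp = TRUE)
  with_seed(config$seeds[["labels"]], {
    delta <- ov$delta
    sdd <- stats::sd(delta)
    z <- if (is.na(sdd) || sdd == 0) {
      warning("degenerate delta-extent distribution; planting null effect")
      rep(0, length(delta))
    } else (delta - mean(delta)) / sdd
    alpha <- stats::qlogis(config$base_high_risk)
    p <- stats::plogis(alpha + config$beta * z)
    high <- NULL
    for (try in 1:20) {
      high <- stats::rbinom(length(p), 1, p) == 1
      if (any(high) && !all(high)) break
      warning("degenerate single-class label draw; resampling")
    }
    if (all(high) || !any(high))
      stop("could not draw both classes after bounded retries")

    n <- length(high)
    cat_start <- character(n); cat_end <- character(n)
    p_up <- config$high_mix[["uplisted"]] / sum(config$high_mix)
    p_down <- config$low_mix[["downlisted"]] / sum(config$low_mix)
    for (i in seq_len(n)) {
      if (high[i]) {
        if (stats::runif(1) < p_up) {
          s <- sample(c("LC", "NT", "VU", "EN"), 1,
                      prob = c(0.5, 0.25, 0.15, 0.1))
          cat_start[i] <- s
          cat_end[i] <- rl_categories()[rl_rank(s) + 2L]
        } else {
          s <- sample(c("NT", "VU", "EN", "CR"), 1,
                      prob = c(0.45, 0.3, 0.2, 0.05))
          cat_start[i] <- s
          cat_end[i] <- s
        }
      } else {
        if (stats::runif(1) < p_down) {
          s <- sample(c("NT", "VU", "EN", "CR"), 1)
          cat_start[i] <- s
          cat_end[i] <- rl_categories()[rl_rank(s)]
        } else {
          cat_start[i] <- "LC"
          cat_end[i] <- "LC"
        }
      }
    }
    ids <- vapply(masks, function(m) m$species_id, character(1))
    histories <- data.frame(species_id = ids, cat_start = cat_start,
                            cat_end = cat_end)
    truth <- data.frame(species_id = ids, delta = delta, z = z, p = p,
                        label = ifelse(high, "high-risk", "low-risk"))
    attr(truth, "t_star") <- config$t_star
    attr(truth, "strict_t") <- t
    attr(truth, "beta") <- config$beta
    attr(truth, "alpha") <- alpha
    list(histories = histories, labels = classify_species(histories),
         truth = truth)
  })
}

#' Generate a full synthetic dataset
#'
#' Convenience wrapper: landscape, HFP maps for both epochs, species and
#' planted transitions under one root seed.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{config}, \code{grid}, \code{stacks},
#'   \code{hfp93}, \code{hfp09}, \code{species} (see
#'   \code{\link{generate_species}}) and \code{transitions} (see
#'   \code{\link{generate_transitions}}).
#' @export
simulate_dataset <- function(config = sim_config()) {
  land <- generate_landscape(config)
  hfp93 <- build_hfp(land$stack93)
  hfp09 <- build_hfp(land$stack09)
  species <- generate_species(config, hfp93$grid)
  trans <- generate_transitions(config, species$masks, hfp93, hfp09)
  list(config = config, grid = hfp93$grid,
       stacks = land[c("stack93", "stack09")],
       hfp93 = hfp93, hfp09 = hfp09, species = species, transitions = trans)
}
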