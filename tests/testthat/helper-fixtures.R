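# Shared fixtures: all generated in code, no files.

FAR <- 999  # "no feature anywhere near" distance, km

# A stack with every pressure at zero (distances far beyond influence).
zero_layers <- function(grid) {
  z <- matrix(0, grid$nrow, grid$ncol)
  far <- matrix(FAR, grid$nrow, grid$ncol)
  list(built = z, crop = z, pasture = z, popdensity = z, nightlights = z,
       railways = far, roads = far, waterways = far)
}

zero_stack <- function(grid, epoch = 1993) {
  pressure_stack(zero_layers(grid), grid, epoch = epoch)
}

# Stack with a single named layer set to given values.
one_layer_stack <- function(grid, layer, values, epoch = 1993) {
  ls <- zero_layers(grid)
  ls[[layer]] <- values
  pressure_stack(ls, grid, epoch = epoch)
}

# Small-but-complete synthetic world used where full scale is not needed.
small_sim <- function(seed = 1, ...) {
  sim_config(seed = seed, nrow = 60, ncol = 60, n_species = 40,
             n_settlements = 4, n_roads = 3, n_rails = 1, n_rivers = 2, ...)
}

# Random integer HFP map for histogram-vs-loop comparisons.
random_hfp <- function(grid, seed, nodata_frac = 0) {
  set.seed(seed)
  v <- matrix(sample(0:50, grid$nrow * grid$ncol, replace = TRUE),
              grid$nrow, grid$ncol)
  if (nodata_frac > 0)
    v[sample(length(v), round(nodata_frac * length(v)))] <- NA
  raster_layer(v, grid)
}

# Synthetic feature table with a planted separable (or null) signal;
# bypasses the landscape for fast model tests.
toy_features <- function(n = 100, seed = 1, separation = 2) {
  set.seed(seed)
  lab <- rep(c("low-risk", "high-risk"), length.out = n)
  sig <- ifelse(lab == "high-risk", separation, 0) + rnorm(n)
  ov <- data.frame(species_id = sprintf("s%03d", 1:n), t = 2L,
                   extent93 = plogis(rnorm(n)), extent09 = plogis(sig),
                   delta = 0, clamped = TRUE)
  ov$delta <- pmax(0, ov$extent09 - ov$extent93)
  cov <- data.frame(
    species_id = ov$species_id,
    popdensity = rlnorm(n), pop_growth = rnorm(n), travel_time = rlnorm(n),
    taxon_order = sample(c("Rodentia", "Carnivora", "Primates"), n, TRUE),
    gestation_length = rlnorm(n, 4), weaning_age = rlnorm(n, 3),
    body_mass = rlnorm(n, 8), diet = sample(c("carnivore", "herbivore",
                                              "omnivore"), n, TRUE),
    habitat_class = sample(c("forest", "grassland", "desert"), n, TRUE),
    ndvi = runif(n), tree_cover = runif(n, 0, 100),
    habitat_prevalence = runif(n))
  lab_df <- data.frame(species_id = ov$species_id, risk_class = lab)
  assemble_features(ov, cov, lab_df, 2L)
}
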