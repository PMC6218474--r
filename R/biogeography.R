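#' Biogeographic realm codes
#' @return named integer vector mapping the six realm codes to raster values.
#' @export
realm_codes <- function() {
  c(AA = 1L, AT = 2L, IM = 3L, `NA` = 4L, NT = 5L, PA = 6L)
}

#' Assign a species to the unit holding the majority of its range
#'
#' A species belongs to a unit (realm or biome-realm) only if strictly more
#' than half of its range cells fall in that unit; otherwise it is
#' unassigned. Membership is computed over the same cell masks used for the
#' overlap statistics (equal-area cells).
#'
#' @param mask a \code{range_mask}.
#' @param unit_raster integer-coded \code{hfp_raster} of units on the HFP
#'   grid.
#' @return list: \code{unit} (integer code or \code{NA}), \code{fraction}
#'   (share of valid range cells in the winning unit).
#' @export
assign_realm <- function(mask, unit_raster) {
  v <- mask_values(mask, unit_raster)
  v <- v[!is.na(v)]
  if (!length(v)) return(list(unit = NA_integer_, fraction = NA_real_))
  tab <- table(v)
  frac <- max(tab) / length(v)
  win <- as.integer(names(tab)[which.max(tab)])
  if (frac > 0.5) list(unit = win, fraction = frac)
  else list(unit = NA_integer_, fraction = frac)
}

#' Assign all species to realms and biome-realms
#'
#' @param masks list of \code{range_mask} objects.
#' @param realm_raster integer realm raster.
#' @param biome_realm_raster optional integer biome-realm raster.
#' @return data.frame: \code{species_id}, \code{realm}, \code{realm_fraction},
#'   and if provided \code{biome_realm}, \code{biome_realm_fraction}.
#' @export
assign_realms <- function(masks, realm_raster, biome_realm_raster = NULL) {
  rows <- lapply(masks, function(m) {
    a <- assign_realm(m, realm_raster)
    out <- data.frame(species_id = m$species_id, realm = a$unit,
                      realm_fraction = a$fraction)
    if (!is.null(biome_realm_raster)) {
      b <- assign_realm(m, biome_realm_raster)
      out$biome_realm <- b$unit
      out$biome_realm_fraction <- b$fraction
    }
    out
  })
  do.call(rbind, rows)
}

#' Retain biome-realms with enough species in both transition classes
#'
#' @param assignments data.frame from \code{\link{assign_realms}} with a
#'   \code{biome_realm} (or \code{realm}) column.
#' @param labels label table with \code{species_id} and \code{risk_class}.
#' @param unit_col which assignment column defines the unit.
#' @param min_per_class minimum species per class (default 5 low + 5 high).
#' @return named list unit -> character vector of species ids (possibly
#'   empty list).
#' @export
filter_biome_realms <- function(assignments, labels,
                                unit_col = "biome_realm", min_per_class = 5) {
  df <- merge(assignments, labels[, c("species_id", "risk_class")],
              by = "species_id")
  df <- df[!is.na(df[[unit_col]]), ]
  out <- list()
  for (u in sort(unique(df[[unit_col]]))) {
    d <- df[df[[unit_col]] == u, ]
    n_low <- sum(d$risk_class == "low-risk")
    n_high <- sum(d$risk_class == "high-risk")
    if (n_low >= min_per_class && n_high >= min_per_class)
      out[[as.character(u)]] <- d$species_id
  }
  out
}

#' Threshold of peak mean change for the positive group
#'
#' The per-unit summary statistic mapped in regional analyses: the threshold
#' at which the high-risk group's mean extent delta is largest (ties toward
#' the lowest threshold).
#'
#' @param sweep a \code{group_sweep}.
#' @return integer threshold.
#' @export
peak_change_threshold <- function(sweep) {
  stopifnot(inherits(sweep, "group_sweep"))
  sweep$t[which.max(sweep$mean_delta_pos)]
}

#' Sweep and model restricted to one realm's species
#'
#' Runs \code{\link{group_sweep}}, \code{\link{effect_profile}},
#' \code{\link{peak_change_threshold}} and \code{\link{threshold_selection}}
#' on the species assigned to one realm. Units with too few species in
#' either class are skipped with a message (a \code{realm_skip} object
#' carrying the reason is returned instead).
#'
#' @param realm integer realm code.
#' @param assignments data.frame from \code{\link{assign_realms}}.
#' @param overlaps,labels,covariates as in the global analysis.
#' @param t_grid thresholds for model selection.
#' @param settings an \code{\link{rf_settings}}.
#' @return list of class \code{realm_report} (\code{realm}, \code{n},
#'   \code{sweep}, \code{effect_profile}, \code{peak_change_t},
#'   \code{selection}), or of class \code{realm_skip} if skipped.
#' @export
per_realm_analysis <- function(realm, assignments, overlaps, labels,
                               covariates, t_grid = 0:49,
                               settings = rf_settings()) {
  ids <- assignments$species_id[!is.na(assignments$realm) &
                                  assignments$realm == realm]
  lab <- labels[labels$species_id %in% ids, , drop = FALSE]
  counts <- table(factor(lab$risk_class, c("low-risk", "high-risk")))
  if (any(counts < settings$folds)) {
    msg <- sprintf("realm %s skipped: class counts low/high = %d/%d (< %d)",
                   realm, counts[1], counts[2], settings$folds)
    message(msg)
    return(structure(list(realm = realm, skip_reason = msg),
                     class = "realm_skip"))
  }
  ov <- overlaps[overlaps$species_id %in% ids, , drop = FALSE]
  sweep <- group_sweep(ov, lab)
  sel <- threshold_selection(ov, covariates[covariates$species_id %in% ids, ,
                                            drop = FALSE],
                             lab, t_grid = t_grid, settings = settings)
  structure(list(realm = realm, n = nrow(lab), sweep = sweep,
                 effect_profile = effect_profile(sweep),
                 peak_change_t = peak_change_threshold(sweep),
                 selection = sel),
            class = "realm_report")
}
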