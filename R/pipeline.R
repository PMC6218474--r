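#' Pipeline run configuration
#'
#' Validated bundle of everything a full synthetic-to-report run needs.
#' Persisted verbatim into the run manifest so a run can be reproduced
#' exactly.
#'
#' @param out_dir output directory (created if needed).
#' @param seed root seed; propagated to the simulation and model settings.
#' @param sim a \code{\link{sim_config}} (defaults to one built from
#'   \code{seed}).
#' @param t_grid thresholds for the sweep stage.
#' @param model_t_grid thresholds scanned by the model-selection stage (the
#'   expensive part; defaults to the full grid).
#' @param clamp apply the "no change" rule to extent deltas.
#' @param rf an \code{\link{rf_settings}} (seeded from \code{seed} by
#'   default).
#' @param share_digits decimals for reported percentage shares.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(out_dir, seed = 1, sim = sim_config(seed = seed),
                       t_grid = 0:49, model_t_grid = t_grid, clamp = TRUE,
                       rf = rf_settings(seed = seed), share_digits = 1) {
  stopifnot(is.character(out_dir), length(out_dir) == 1,
            inherits(sim, "sim_config"), inherits(rf, "rf_settings"),
            all(t_grid %in% 0:49), all(model_t_grid %in% 0:49),
            length(model_t_grid) >= 2, is.logical(clamp))
  structure(list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
                 t_grid = sort(unique(as.integer(t_grid))),
                 model_t_grid = sort(unique(as.integer(model_t_grid))),
                 clamp = clamp, rf = rf, share_digits = share_digits),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys: \code{out_dir}, \code{seed}, \code{t_grid} /
#' \code{model_t_grid} (as \code{[min, max]} or explicit lists),
#' \code{clamp}, and optional \code{sim:} and \code{rf:} blocks whose entries
#' override \code{\link{sim_config}} / \code{\link{rf_settings}} arguments.
#'
#' @param path YAML file.
#' @param out_dir override for the output directory.
#' @return a \code{\link{run_config}}.
#' @export
read_run_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  seed <- y$seed %||% 1
  grid_of <- function(g, default) {
    if (is.null(g)) default
    else if (length(g) == 2 && !is.null(names(g)) &&
             all(names(g) %in% c("min", "max"))) g$min:g$max
    else unlist(g)
  }
  sim <- do.call(sim_config, c(list(seed = seed), y$sim))
  rf <- do.call(rf_settings, c(list(seed = seed), y$rf))
  run_config(out_dir = out_dir %||% y$out_dir %||% stop("out_dir required"),
             seed = seed, sim = sim,
             t_grid = grid_of(y$t_grid, 0:49),
             model_t_grid = grid_of(y$model_t_grid,
                                    grid_of(y$t_grid, 0:49)),
             clamp = y$clamp %||% TRUE, rf = rf,
             share_digits = y$share_digits %||% 1)
}

write_json_report <- function(x, path) {
  x$schema_version <- "1.0"
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(path)
}

#' Run the full pipeline on synthetic data
#'
#' Executes the seven stages simulate, build-hfp (including the change
#' product), classify, overlap, sweep, model and realms, writing plain-text
#' outputs and a manifest (stage list, output checksums, seed, package
#' version) into \code{out_dir}. A failed stage halts the run; the manifest
#' then records the failure and the partial outputs. Rerunning with the same
#' configuration reproduces byte-identical outputs.
#'
#' @param config a \code{\link{run_config}}.
#' @return the output directory, invisibly; the manifest is
#'   \code{file.path(out_dir, "manifest.json")}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  stages <- list()
  note_stage <- function(name, files) {
    sums <- tools::md5sum(files)
    names(sums) <- basename(files)  # manifest is location-independent
    stages[[length(stages) + 1]] <<- list(name = name, status = "ok",
                                          outputs = as.list(sums))
  }
  finish_manifest <- function(status = "ok", error = NULL) {
    manifest <- list(
      status = status, error = error, seed = config$seed,
      package = "footprintr",
      version = as.character(utils::packageVersion("footprintr")),
      clamp = config$clamp, t_grid = config$t_grid,
      model_t_grid = config$model_t_grid,
      sim = unclass(config$sim)[setdiff(names(config$sim), "seeds")],
      rf = unclass(config$rf), stages = stages)
    write_json_report(manifest, out("manifest.json"))
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stages[[length(stages) + 1]] <<- list(name = name, status = "failed",
                                            outputs = list())
      finish_manifest("failed", conditionMessage(e))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # -- simulate -------------------------------------------------------------
  data <- run_stage("simulate", {
    d <- simulate_dataset(config$sim)
    write_ranges_geojson(d$species$polygons, out("ranges.geojson"))
    utils::write.csv(d$species$covariates, out("covariates.csv"),
                     row.names = FALSE)
    utils::write.csv(d$transitions$histories, out("categories.csv"),
                     row.names = FALSE)
    write_json_report(list(
      t_star = attr(d$transitions$truth, "t_star"),
      strict_t = attr(d$transitions$truth, "strict_t"),
      beta = attr(d$transitions$truth, "beta"),
      alpha = attr(d$transitions$truth, "alpha"),
      species = d$transitions$truth), out("truth.json"))
    write_asc(d$species$realm_raster, out("realms.asc"))
    write_asc(d$species$biome_realm_raster, out("biome_realms.asc"))
    note_stage("simulate", out(c("ranges.geojson", "covariates.csv",
                                 "categories.csv", "truth.json", "realms.asc",
                                 "biome_realms.asc")))
    d
  })

  # -- build-hfp (incl. change product) ------------------------------------
  change <- run_stage("build-hfp", {
    write_asc(data$hfp93, out("hfp1993.asc"))
    write_asc(data$hfp09, out("hfp2009.asc"))
    ch <- hfp_change(data$hfp93, data$hfp09,
                     clamp_decreases = config$clamp)
    write_asc(ch$delta, out("hfp_delta.asc"))
    write_matrix_csv(ch$matrix, out("hfp_transitions.csv"))
    note_stage("build-hfp", out(c("hfp1993.asc", "hfp2009.asc",
                                  "hfp_delta.asc", "hfp_transitions.csv")))
    ch
  })

  # -- classify -------------------------------------------------------------
  labels <- run_stage("classify", {
    filt <- filter_species(data$transitions$histories)
    lab <- classify_species(filt$retained)
    tab <- tabulate_transitions(filt$retained)
    utils::write.csv(lab, out("labels.csv"), row.names = FALSE)
    write_matrix_csv(tab$matrix, out("category_transitions.csv"))
    write_json_report(list(
      n = tab$n,
      shares_pct = as.list(round(tab$shares, config$share_digits)),
      excluded = filt$excluded), out("classification_summary.json"))
    note_stage("classify", out(c("labels.csv", "category_transitions.csv",
                                 "classification_summary.json")))
    lab
  })

  # -- overlap --------------------------------------------------------------
  overlaps <- run_stage("overlap", {
    ov <- overlap_table(data$species$masks, data$hfp93, data$hfp09,
                        t = config$t_grid, clamp = config$clamp)
    utils::write.csv(ov, out("overlaps.csv"), row.names = FALSE)
    note_stage("overlap", out("overlaps.csv"))
    ov
  })

  # -- sweep ----------------------------------------------------------------
  sweep <- run_stage("sweep", {
    sw <- group_sweep(overlaps, labels)
    peaks <- effect_profile(sw)
    utils::write.csv(as.data.frame(sw), out("sweep.csv"), row.names = FALSE)
    write_json_report(list(
      t_peak_extent = peaks$t_peak_extent,
      t_peak_delta = peaks$t_peak_delta,
      threshold_convention = "strict: high HFP means HFP > t (HFP >= t + 1)"),
      out("sweep_peaks.json"))
    note_stage("sweep", out(c("sweep.csv", "sweep_peaks.json")))
    sw
  })

  # -- model ----------------------------------------------------------------
  selection <- run_stage("model", {
    sel <- threshold_selection(overlaps, data$species$covariates, labels,
                               t_grid = config$model_t_grid,
                               settings = config$rf)
    best <- sel$reports[[as.character(sel$best_t)]]
    utils::write.csv(sel$curve, out("threshold_curve.csv"), row.names = FALSE)
    utils::write.csv(best$importance, out("importance.csv"),
                     row.names = FALSE)
    write_json_report(list(
      best_t = sel$best_t,
      threshold_convention = "strict: high HFP means HFP > t (HFP >= t + 1)",
      accuracy = best$accuracy, sensitivity = best$sensitivity,
      specificity = best$specificity, tss = best$tss,
      confusion = as.list(as.data.frame(best$confusion)),
      settings = best$settings), out("model_report.json"))
    note_stage("model", out(c("threshold_curve.csv", "importance.csv",
                              "model_report.json")))
    sel
  })

  # -- realms ---------------------------------------------------------------
  run_stage("realms", {
    assignments <- assign_realms(data$species$masks,
                                 data$species$realm_raster,
                                 data$species$biome_realm_raster)
    utils::write.csv(assignments, out("realm_assignments.csv"),
                     row.names = FALSE)
    units <- filter_biome_realms(assignments, labels)
    reports <- list()
    peak_tab <- list()
    for (realm in sort(unique(assignments$realm[!is.na(assignments$realm)]))) {
      rr <- per_realm_analysis(realm, assignments, overlaps, labels,
                               data$species$covariates,
                               t_grid = config$model_t_grid,
                               settings = config$rf)
      if (inherits(rr, "realm_skip")) {
        reports[[as.character(realm)]] <- list(
          realm = realm, skipped = rr$skip_reason)
      } else {
        reports[[as.character(realm)]] <- list(
          realm = realm, n = rr$n, best_t = rr$selection$best_t,
          t_peak_delta = rr$effect_profile$t_peak_delta,
          peak_change_t = rr$peak_change_t,
          tss = rr$selection$reports[[as.character(rr$selection$best_t)]]$tss)
      }
    }
    for (u in names(units)) {
      ids <- units[[u]]
      sw <- group_sweep(overlaps[overlaps$species_id %in% ids, ],
                        labels[labels$species_id %in% ids, ])
      peak_tab[[u]] <- data.frame(biome_realm = u, n = length(ids),
                                  peak_change_t = peak_change_threshold(sw))
    }
    peak_df <- if (length(peak_tab)) do.call(rbind, peak_tab) else
      data.frame(biome_realm = character(0), n = integer(0),
                 peak_change_t = integer(0))
    utils::write.csv(peak_df, out("biome_realm_thresholds.csv"),
                     row.names = FALSE)
    write_json_report(list(realms = reports,
                           retained_biome_realms = names(units)),
                      out("realm_reports.json"))
    note_stage("realms", out(c("realm_assignments.csv",
                               "biome_realm_thresholds.csv",
                               "realm_reports.json")))
    NULL
  })

  finish_manifest("ok")
  invisible(config$out_dir)
}
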