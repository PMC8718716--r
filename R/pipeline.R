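#' Pipeline configuration
#'
#' Aggregates every tunable constant of the workflow with its canonical
#' default: 120 m shoreline buffer, 95% Secchi quantile, 24 h match-up
#' window, 3x3 macropixel with >= 6 valid pixels and std/median < 0.20,
#' +-5% quantile bands, >= 50% scene coverage, and the canonical
#' calibration coefficients (21, 0.77, 1.04). Synthetic-world parameters
#' (grid, lake shape, chlorophyll level, noise, cloudiness, survey design)
#' live here too so a single config reproduces an entire experiment.
#'
#' @param buffer_distance metres, >= 0
#' @param secchi_quantile in (0, 1)
#' @param matchup_window_hours > 0
#' @param macropixel_size odd, >= 1
#' @param min_valid in 1..macropixel_size^2
#' @param homogeneity_threshold > 0
#' @param band_tolerance >= 0
#' @param coverage_threshold in `[0, 1]`
#' @param coefficients a [calibration_coefficients()]
#' @param seed master experiment seed
#' @param rows,cols,cell_size,lake_radius,lake_max_depth synthetic grid
#' @param base_chl,pattern,noise_cv,n_scenes,cloud_fraction synthetic scenes
#' @param n_stations,time_offsets_h,measurement_cv,n_secchi synthetic survey
#' @return object of class `pipeline_config`
#' @export
pipeline_config <- function(buffer_distance = 120, secchi_quantile = 0.95,
                            matchup_window_hours = 24, macropixel_size = 3L,
                            min_valid = 6L, homogeneity_threshold = 0.20,
                            band_tolerance = 0.05, coverage_threshold = 0.5,
                            coefficients = calibration_coefficients(),
                            seed = 1L,
                            rows = 50L, cols = 50L, cell_size = 60,
                            lake_radius = 900, lake_max_depth = 25,
                            base_chl = 10, pattern = "gradient",
                            noise_cv = 0.1, n_scenes = 40L,
                            cloud_fraction = 0.2,
                            n_stations = 3L, time_offsets_h = c(-6, 2, 10),
                            measurement_cv = 0.1, n_secchi = 200L) {
  stopifnot(buffer_distance >= 0, secchi_quantile > 0, secchi_quantile < 1,
            matchup_window_hours > 0, macropixel_size %% 2L == 1L,
            min_valid >= 1L, min_valid <= macropixel_size^2,
            homogeneity_threshold > 0, band_tolerance >= 0,
            coverage_threshold >= 0, coverage_threshold <= 1,
            inherits(coefficients, "calibration_coefficients"))
  cfg <- list(buffer_distance = buffer_distance,
              secchi_quantile = secchi_quantile,
              matchup_window_hours = matchup_window_hours,
              macropixel_size = as.integer(macropixel_size),
              min_valid = as.integer(min_valid),
              homogeneity_threshold = homogeneity_threshold,
              band_tolerance = band_tolerance,
              coverage_threshold = coverage_threshold,
              coefficients = coefficients, seed = as.integer(seed),
              rows = as.integer(rows), cols = as.integer(cols),
              cell_size = cell_size, lake_radius = lake_radius,
              lake_max_depth = lake_max_depth, base_chl = base_chl,
              pattern = pattern, noise_cv = noise_cv,
              n_scenes = as.integer(n_scenes),
              cloud_fraction = cloud_fraction,
              n_stations = as.integer(n_stations),
              time_offsets_h = time_offsets_h,
              measurement_cv = measurement_cv,
              n_secchi = as.integer(n_secchi))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Stable audit hash of a configuration
#'
#' A deterministic 32-bit djb2-style hash of the canonical deparse of the
#' config, stamped into every output for provenance. An audit tag, not a
#' cryptographic digest.
#'
#' @param config a [pipeline_config()]
#' @return 8-character hex string
#' @export
config_hash <- function(config) {
  s <- paste(deparse(config[order(names(unclass(config)))]), collapse = "")
  h <- 5381
  for (k in utf8ToInt(s)) h <- (h * 33 + k) %% 4294967291
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Build the synthetic world for a config: geometry + valid-water mask,
# truth, scenes, secchi samples and survey.
simulate_world <- function(config) {
  geom <- generate_lake_geometry(config$rows, config$cols, config$cell_size,
                                 shape = list(radius = config$lake_radius,
                                              max_depth = config$lake_max_depth),
                                 seed = derive_seed(config$seed, "geometry"))
  secchi <- generate_secchi_samples(config$n_secchi,
                                    seed = derive_seed(config$seed, "secchi"))
  geom$valid_water_mask <- build_valid_water_mask(
    geom, secchi, config$buffer_distance, config$secchi_quantile)
  truth <- lake_truth(geom, base_chl = config$base_chl,
                      pattern = config$pattern, noise_cv = config$noise_cv,
                      seed = derive_seed(config$seed, "pattern"))
  scenes <- generate_scene_series(truth, config$n_scenes,
                                  cloud_fraction = config$cloud_fraction,
                                  seed = derive_seed(config$seed, "series"))
  # stations near the deepest part of the lake (monitoring practice)
  ord <- order(geom$bathymetry, decreasing = TRUE)
  deep <- arrayInd(ord[seq_len(config$n_stations)], dim(geom$lake_mask))
  stations <- data.frame(i = deep[, 1L], j = deep[, 2L])
  samples <- generate_insitu_survey(truth, scenes, stations,
                                    time_offsets_h = config$time_offsets_h,
                                    measurement_cv = config$measurement_cv,
                                    seed = derive_seed(config$seed, "survey"))
  list(geometry = geom, truth = truth, scenes = scenes,
       secchi = secchi, samples = samples)
}

#' Run the pipeline
#'
#' Orchestrates the stages behind one entry point. `"simulate"` writes the
#' synthetic scene series, in-situ CSV, lake outline and bathymetry;
#' `"mask"` writes the valid-water mask and buffered outline; `"matchup"`
#' writes the QC'd match-up table; `"calibrate"` the refit coefficients
#' and diagnostics as JSON; `"patchmap"` the 3-band quantile-frequency
#' composite; `"all"` chains everything on the synthetic world. Every
#' output carries the config hash; per-stage record counts are logged
#' with `message()`.
#'
#' @param stage one of `"all"`, `"simulate"`, `"mask"`, `"matchup"`,
#'   `"calibrate"`, `"patchmap"`
#' @param config a [pipeline_config()]
#' @param out_dir output directory (created if needed)
#' @return invisibly, a list with the stage artifacts and file paths
#' @export
run_pipeline <- function(stage = c("all", "simulate", "mask", "matchup",
                                   "calibrate", "patchmap"),
                         config = pipeline_config(), out_dir = ".") {
  stage <- match.arg(stage)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  world <- simulate_world(config)
  paths <- list()

  if (stage %in% c("all", "simulate")) {
    paths$series <- file.path(out_dir, "scene_series.txt")
    write_scene_series(world$scenes, paths$series, config_hash = hash)
    paths$insitu <- file.path(out_dir, "insitu_chl.csv")
    write_insitu_csv(world$samples, paths$insitu)
    paths$outline <- file.path(out_dir, "lake_outline.geojson")
    write_lake_geojson(world$geometry$polygon, paths$outline,
                       properties = list(config_hash = hash))
    paths$bathymetry <- file.path(out_dir, "bathymetry.asc")
    write_ascii_grid(world$geometry$bathymetry, paths$bathymetry,
                     world$geometry$transform)
    message("simulate: ", length(world$scenes), " scenes, ",
            nrow(world$samples), " in-situ samples, ",
            sum(world$geometry$lake_mask), " lake pixels [", hash, "]")
  }
  if (stage %in% c("all", "mask")) {
    vwm <- world$geometry$valid_water_mask
    paths$valid_water <- file.path(out_dir, "valid_water_mask.asc")
    write_ascii_grid(vwm + 0, paths$valid_water, world$geometry$transform)
    buffered <- buffer_shoreline(world$geometry$polygon,
                                 config$buffer_distance)
    paths$buffered <- file.path(out_dir, "valid_water_outline.geojson")
    write_lake_geojson(buffered, paths$buffered,
                       properties = list(
                         buffer_distance_m = config$buffer_distance,
                         secchi_exclusion_m = attr(vwm, "exclusion_depth_m"),
                         config_hash = hash))
    message("mask: ", sum(vwm), " of ", sum(world$geometry$lake_mask),
            " lake pixels valid water (exclusion depth ",
            round(attr(vwm, "exclusion_depth_m"), 2), " m)")
  }
  matchups <- NULL
  if (stage %in% c("all", "matchup", "calibrate")) {
    matchups <- build_matchups(world$samples, world$scenes,
                               window_hours = config$matchup_window_hours,
                               min_valid = config$min_valid,
                               homogeneity_threshold = config$homogeneity_threshold,
                               macropixel_size = config$macropixel_size)
    reasons <- table(matchups$rejection_reason[!matchups$passed])
    message("matchup: ", nrow(matchups), " candidates, ",
            sum(matchups$passed), " passed",
            if (length(reasons)) paste0(" (rejected: ",
                paste(names(reasons), reasons, sep = "=", collapse = ", "), ")"))
  }
  if (stage %in% c("all", "matchup")) {
    paths$matchups <- file.path(out_dir, "matchups.csv")
    out <- matchups
    out$datetime <- NULL
    out$config_hash <- rep(hash, nrow(out))
    utils::write.csv(out, paths$matchups, row.names = FALSE)
  }
  if (stage %in% c("all", "calibrate")) {
    passing <- matchups[matchups$passed, , drop = FALSE]
    fit <- fit_regional_coefficients(
      data.frame(a_pig = passing$a_pig, a_det = passing$a_det,
                 a_cdom = passing$a_cdom, chl_insitu = passing$chl_insitu),
      init = config$coefficients)
    paths$fit <- file.path(out_dir, "calibration_fit.json")
    jsonlite::write_json(list(coefficients = unclass(fit$coefficients),
                              r_squared = fit$r_squared, rmse = fit$rmse,
                              n = fit$n, convergence = fit$convergence,
                              config_hash = hash),
                         paths$fit, auto_unbox = TRUE, digits = NA)
    message("calibrate: n=", fit$n, " r2=", round(fit$r_squared, 3),
            " rmse=", signif(fit$rmse, 3), " A=", signif(fit$coefficients$A, 5),
            " B=", signif(fit$coefficients$B, 5),
            " C=", signif(fit$coefficients$C, 5))
    paths$fit_result <- fit
  }
  if (stage %in% c("all", "patchmap")) {
    comp <- patchiness_composite(world$scenes,
                                 world$geometry$valid_water_mask,
                                 tolerance = config$band_tolerance,
                                 coverage_threshold = config$coverage_threshold)
    paths$composite <- file.path(out_dir, "chl_spatial_variability")
    write_composite_raster(comp, paths$composite)
    message("patchmap: ", comp$n_scenes, " of ", comp$n_scenes_total,
            " scenes met the coverage rule")
    paths$composite_result <- comp
  }
  invisible(c(paths, list(world = world, config_hash = hash)))
}
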