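# Shared fixture builders. Everything is generated in code at test time;
# nothing is read from disk.

# a circular 50x50 lake at 60 m cells, radius 900 m (~707 interior cells)
circle_geometry <- function(rows = 50L, cols = 50L, radius = 900,
                            max_depth = 25, seed = 1L) {
  generate_lake_geometry(rows, cols, 60,
                         shape = list(radius = radius, irregularity = 0,
                                      max_depth = max_depth),
                         seed = seed)
}

# small world for matchup / spatial tests: geometry + truth + scenes
small_world <- function(n_scenes = 5L, pattern = "flat", noise_cv = 0,
                        cloud_fraction = 0, rows = 24L, cols = 24L,
                        radius = 550, base_chl = 10, seed = 1L,
                        temporal_factors = NULL) {
  geom <- generate_lake_geometry(rows, cols, 60,
                                 shape = list(radius = radius,
                                              irregularity = 0,
                                              max_depth = 25),
                                 seed = seed)
  truth <- lake_truth(geom, base_chl = base_chl, pattern = pattern,
                      noise_cv = noise_cv,
                      temporal_factors = temporal_factors, seed = seed)
  scenes <- generate_scene_series(truth, n_scenes,
                                  cloud_fraction = cloud_fraction,
                                  seed = seed)
  list(geometry = geom, truth = truth, scenes = scenes)
}

# Straight-line re-implementation of the three printed match-up rules
# (24 h window, >= 6 valid of the 3x3 block, population std / median
# < 0.20, mean aggregation). Independent of build_matchups: direct index
# arithmetic, no package helpers beyond valid_pixel_mask input.
oracle_matchups <- function(samples, scenes, valid_masks,
                            window_hours = 24, min_valid = 6L,
                            threshold = 0.20) {
  out <- list()
  for (si in seq_len(nrow(samples))) for (ci in seq_along(scenes)) {
    sc <- scenes[[ci]]
    dt <- as.numeric(samples$datetime[si] - sc$timestamp, units = "hours")
    if (abs(dt) > window_hours) next
    tr <- sc$transform
    j0 <- floor((samples$x[si] - tr$x0) / tr$cell) + 1
    i0 <- floor((tr$y0 - samples$y[si]) / tr$cell) + 1
    vals <- c(); nv <- 0L
    for (di in -1:1) for (dj in -1:1) {
      i <- i0 + di; j <- j0 + dj
      if (i >= 1 && i <= tr$nrow && j >= 1 && j <= tr$ncol &&
          isTRUE(valid_masks[[ci]][i, j]) && !is.na(sc$chl[i, j])) {
        vals <- c(vals, sc$chl[i, j]); nv <- nv + 1L
      }
    }
    rec <- list(sample_idx = si, scene_idx = ci, n_valid = nv,
                passed = FALSE, reason = NA_character_,
                satellite_chl = NA_real_)
    if (nv < min_valid) {
      rec$reason <- "insufficient_valid"
    } else {
      med <- stats::median(vals)
      if (med <= 0) {
        rec$reason <- "nonpositive_median"
      } else if (sqrt(mean((vals - mean(vals))^2)) / med >= threshold) {
        rec$reason <- "inhomogeneous"
      } else {
        rec$passed <- TRUE
        rec$satellite_chl <- mean(vals)
      }
    }
    out[[length(out) + 1L]] <- rec
  }
  do.call(rbind, lapply(out, as.data.frame))
}

# Literal restatement of the Table-2 validity rule for one bit pattern.
oracle_valid_bits <- function(code) {
  bits <- flag_bits()
  raised <- names(bits)[bitwAnd(code, bits) != 0L]
  all(c("IDEPIX_WATER", "SHORE_SHALLOW_BUFFER") %in% raised) &&
    !any(c("IDEPIX_CLOUD", "IDEPIX_CLOUD_BUFFER", "IDEPIX_CLOUD_SHADDOW",
           "IDEPIX_CIRRUS_SURE", "RTOSA_OOS", "RTOSA_OOR", "RHOW_OOR",
           "RHOW_OOS", "IOP_OOR") %in% raised)
}
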