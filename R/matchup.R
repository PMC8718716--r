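#' Pair in-situ samples with scenes by time
#'
#' All and only the (sample, scene) pairs whose absolute time difference is
#' within the window (inclusive; the window is read as "within 24 hours").
#' A sample may pair with several scenes.
#'
#' @param samples data frame with a `datetime` column (POSIXct UTC)
#' @param scene_times `POSIXct` vector of scene times, or a list of scenes
#'   with `$timestamp`
#' @param window_hours window half-width in hours, default 24
#' @return data frame with `sample_idx`, `scene_idx`, `dt_hours`
#'   (signed, sample minus scene)
#' @export
pair_by_time <- function(samples, scene_times, window_hours = 24) {
  if (is.list(scene_times) && !inherits(scene_times, "POSIXct"))
    scene_times <- do.call(c, lapply(scene_times, `[[`, "timestamp"))
  out <- data.frame(sample_idx = integer(0), scene_idx = integer(0),
                    dt_hours = numeric(0))
  if (length(scene_times) == 0L || nrow(samples) == 0L) return(out)
  st <- as.numeric(samples$datetime)
  sc <- as.numeric(scene_times)
  g <- expand.grid(sample_idx = seq_along(st), scene_idx = seq_along(sc))
  dt <- (st[g$sample_idx] - sc[g$scene_idx]) / 3600
  keep <- abs(dt) <= window_hours
  data.frame(sample_idx = g$sample_idx[keep], scene_idx = g$scene_idx[keep],
             dt_hours = dt[keep])
}

#' Extract the macropixel around a station
#'
#' The `size x size` (default 3x3, i.e. 180 m x 180 m at 60 m pixels) block
#' of chlorophyll values centred on the raster cell containing the station,
#' each paired with its validity bit. Cells outside the raster count as
#' invalid (`NA` value). The centre cell is found with the same affine
#' transform used for rasterization; no sub-pixel interpolation.
#'
#' @param scene a scene with `$chl` and `$transform` (or any list with
#'   those fields)
#' @param x,y station coordinates, projected metres
#' @param valid_mask logical matrix of pixel validity (e.g.
#'   [valid_pixel_mask()] of the scene flags)
#' @param size odd block edge length, default 3
#' @return list with `values` (length `size^2`, `NA` outside raster),
#'   `valid` (logical), `center` (i, j)
#' @export
extract_macropixel <- function(scene, x, y, valid_mask, size = 3L) {
  stopifnot(size >= 1L, size %% 2L == 1L)
  tr <- scene$transform
  ctr <- point_to_cell(tr, x, y)
  if (is.na(ctr$i) || is.na(ctr$j))
    stop("station position (", x, ", ", y, ") is outside the raster")
  h <- (size - 1L) %/% 2L
  ii <- ctr$i + (-h:h); jj <- ctr$j + (-h:h)
  vals <- rep(NA_real_, size * size)
  ok <- rep(FALSE, size * size)
  k <- 0L
  for (i in ii) for (j in jj) {
    k <- k + 1L
    if (i >= 1L && i <= tr$nrow && j >= 1L && j <= tr$ncol) {
      vals[k] <- scene$chl[i, j]
      ok[k] <- isTRUE(valid_mask[i, j]) && !is.na(scene$chl[i, j])
    }
  }
  list(values = vals, valid = ok, center = c(i = ctr$i, j = ctr$j))
}

#' Macropixel homogeneity test
#'
#' The spatial-homogeneity screen for match-ups: the population standard
#' deviation of the valid macropixel values must be less than 20% of their
#' median. The ratio is scale-invariant, so the test is unaffected by
#' multiplying all values by a positive constant.
#'
#' @param values valid macropixel chlorophyll values (>= 1, all finite)
#' @param threshold pass threshold on std/median, default 0.20 (strict:
#'   `ratio < threshold` passes)
#' @return list with `ratio`, `passed`, and `reason`
#'   (`"nonpositive_median"` when the median is <= 0, else `NA`)
#' @export
assess_homogeneity <- function(values, threshold = 0.20) {
  stopifnot(length(values) >= 1L, all(is.finite(values)))
  med <- stats::median(values)
  if (med <= 0)
    return(list(ratio = NA_real_, passed = FALSE,
                reason = "nonpositive_median"))
  sd_pop <- sqrt(mean((values - mean(values))^2))
  ratio <- sd_pop / med
  list(ratio = ratio, passed = ratio < threshold, reason = NA_character_)
}

#' Build quality-controlled match-up records
#'
#' The full QC cascade on every time-window candidate pair: (1) the time
#' window ([pair_by_time()]); (2) at least `min_valid` of the macropixel's
#' cells valid; (3) macropixel homogeneity ([assess_homogeneity()]).
#' `rejection_reason` records the first failed criterion
#' (`"insufficient_valid"`, `"nonpositive_median"`, `"inhomogeneous"`).
#' For passing records the satellite value is the arithmetic mean of the
#' valid macropixel chlorophyll values, and the macropixel-mean absorptions
#' over the same cells are carried along for the calibration refit.
#' Failures are records, not errors.
#'
#' @param samples an `insitu_samples` data frame (columns `x`, `y`,
#'   `datetime`, `chl_mg_m3`, and optionally `station_id`)
#' @param scenes list of scenes with `$chl`, `$flags`, `$transform`,
#'   `$timestamp` and optionally absorption rasters
#' @param window_hours,min_valid,homogeneity_threshold,macropixel_size QC
#'   parameters (defaults 24 h, 6 pixels, 0.20, 3)
#' @return data frame of class `matchup_records`; one row per candidate
#'   pair, with `passed`, `rejection_reason`, `n_valid`,
#'   `homogeneity_ratio`, `satellite_chl` (`NA` unless passed), macropixel
#'   mean `a_pig`/`a_det`/`a_cdom`, and provenance columns
#' @export
build_matchups <- function(samples, scenes, window_hours = 24,
                           min_valid = 6L, homogeneity_threshold = 0.20,
                           macropixel_size = 3L) {
  pairs <- pair_by_time(samples, scenes, window_hours)
  n <- nrow(pairs)
  rec <- data.frame(
    sample_idx = pairs$sample_idx, scene_idx = pairs$scene_idx,
    dt_hours = pairs$dt_hours,
    station_id = if (!is.null(samples$station_id))
      as.character(samples$station_id[pairs$sample_idx]) else
        rep(NA_character_, n),
    chl_insitu = samples$chl_mg_m3[pairs$sample_idx],
    n_valid = rep(0L, n), homogeneity_ratio = rep(NA_real_, n),
    satellite_chl = rep(NA_real_, n),
    a_pig = rep(NA_real_, n), a_det = rep(NA_real_, n),
    a_cdom = rep(NA_real_, n),
    passed = rep(FALSE, n), rejection_reason = rep(NA_character_, n),
    stringsAsFactors = FALSE)
  if (n == 0L) {
    class(rec) <- c("matchup_records", "data.frame")
    return(rec)
  }
  valid_masks <- lapply(scenes, function(s) valid_pixel_mask(s$flags))
  for (r in seq_len(n)) {
    s_i <- pairs$sample_idx[r]; c_i <- pairs$scene_idx[r]
    sc <- scenes[[c_i]]
    mp <- extract_macropixel(sc, samples$x[s_i], samples$y[s_i],
                             valid_masks[[c_i]], size = macropixel_size)
    vals <- mp$values[mp$valid]
    rec$n_valid[r] <- length(vals)
    if (length(vals) < min_valid) {
      rec$rejection_reason[r] <- "insufficient_valid"
      next
    }
    hom <- assess_homogeneity(vals, homogeneity_threshold)
    rec$homogeneity_ratio[r] <- hom$ratio
    if (!hom$passed) {
      rec$rejection_reason[r] <- if (!is.na(hom$reason)) hom$reason else
        "inhomogeneous"
      next
    }
    rec$passed[r] <- TRUE
    rec$satellite_chl[r] <- mean(vals)
    for (v in c("a_pig", "a_det", "a_cdom")) {
      if (!is.null(sc[[v]])) {
        mpv <- extract_macropixel(list(chl = sc[[v]], transform = sc$transform),
                                  samples$x[s_i], samples$y[s_i],
                                  valid_masks[[c_i]], size = macropixel_size)
        rec[[v]][r] <- mean(mpv$values[mp$valid])
      }
    }
  }
  class(rec) <- c("matchup_records", "data.frame")
  rec
}
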