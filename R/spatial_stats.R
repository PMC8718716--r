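#' Scene coverage of the valid-water area
#'
#' Fraction of valid-water pixels that are valid (unflagged) in this
#' scene. A scene participates in the spatial statistics iff its coverage
#' is at least the threshold (default 0.5, inclusive: "at least half of
#' the lake's pixels not obscured").
#'
#' @param scene_valid logical matrix of per-pixel validity for the scene
#' @param valid_water_mask logical matrix (from [build_valid_water_mask()])
#' @return coverage fraction in `[0, 1]`
#' @export
scene_coverage <- function(scene_valid, valid_water_mask) {
  stopifnot(all(dim(scene_valid) == dim(valid_water_mask)))
  denom <- sum(valid_water_mask)
  if (denom == 0L) stop("valid-water mask is empty")
  sum(scene_valid & valid_water_mask) / denom
}

#' Lake-wide chlorophyll quantiles of one scene
#'
#' Q25, Q50 (median) and Q75 of the valid chlorophyll values, under the
#' linear-interpolation quantile rule.
#'
#' @param values valid chlorophyll values of one scene (>= 4)
#' @return object of class `quantile_summary` with `q25`, `q50`, `q75`,
#'   `n_valid`
#' @export
lake_quantiles <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 4L)
    stop("fewer than 4 valid values: scene must be skipped")
  q <- quantile_linear(values, c(0.25, 0.5, 0.75))
  structure(list(q25 = q[1L], q50 = q[2L], q75 = q[3L],
                 n_valid = length(values)),
            class = "quantile_summary")
}

#' Assign pixels to quantile bands
#'
#' For each of the three quantiles q in (Q50, Q25, Q75), a valid pixel is
#' assigned to the band iff `(1 - tolerance) q <= value <= (1 + tolerance) q`
#' (inclusive at both ends, tolerance relative to the quantile; default
#' +-5%). A pixel may fall in several bands when quantiles are close. A
#' zero quantile degenerates the band to exactly-zero pixels.
#'
#' @param chl chlorophyll raster of the scene
#' @param valid logical matrix of pixel validity
#' @param summary a [lake_quantiles()] of the same scene
#' @param tolerance relative half-width of the band, default 0.05
#' @return list of logical matrices `band_q50`, `band_q25`, `band_q75`
#' @export
assign_quantile_bands <- function(chl, valid, summary, tolerance = 0.05) {
  stopifnot(inherits(summary, "quantile_summary"),
            tolerance >= 0, all(dim(chl) == dim(valid)))
  one <- function(q) {
    b <- valid & !is.na(chl) & chl >= (1 - tolerance) * q &
      chl <= (1 + tolerance) * q
    b[is.na(b)] <- FALSE
    b
  }
  list(band_q50 = one(summary$q50), band_q25 = one(summary$q25),
       band_q75 = one(summary$q75))
}

#' Accumulate band assignments into relative frequencies
#'
#' Converts per-scene band memberships into a per-pixel relative frequency
#' (percent). With the default per-pixel denominator, the frequency for a
#' pixel is 100 x (participating scenes in which the pixel was in the
#' band) / (participating scenes in which the pixel was valid) -- pixels
#' under recurrent cloud are not penalized. `denominator = "all_scenes"`
#' divides by the number of participating scenes instead. Pixels valid in
#' no scene get `NA`.
#'
#' @param assignments list (one per participating scene) of
#'   [assign_quantile_bands()] results
#' @param valids list of the matching per-scene validity rasters
#' @param denominator `"per_pixel"` (default) or `"all_scenes"`
#' @return object of class `composite_frequency`: percent rasters
#'   `band_q50`, `band_q25`, `band_q75`, the per-pixel `denominator`
#'   raster, and `n_scenes`
#' @export
accumulate_frequencies <- function(assignments, valids,
                                   denominator = c("per_pixel", "all_scenes")) {
  denominator <- match.arg(denominator)
  stopifnot(length(assignments) >= 1L, length(assignments) == length(valids))
  dims <- dim(valids[[1L]])
  nvalid <- matrix(0L, dims[1L], dims[2L])
  counts <- list(band_q50 = nvalid, band_q25 = nvalid, band_q75 = nvalid)
  for (k in seq_along(assignments)) {
    nvalid <- nvalid + valids[[k]]
    for (b in names(counts)) counts[[b]] <- counts[[b]] + assignments[[k]][[b]]
  }
  denom <- if (denominator == "per_pixel") nvalid else
    matrix(length(assignments), dims[1L], dims[2L])
  freq <- lapply(counts, function(cnt) {
    f <- 100 * cnt / denom
    f[nvalid == 0L] <- NA_real_
    f
  })
  structure(c(freq, list(denominator = nvalid, n_scenes = length(assignments),
                         denominator_rule = denominator)),
            class = "composite_frequency")
}

#' Quantile-frequency patchiness composite over a scene series
#'
#' The end-to-end spatial statistic: for every scene with at least
#' `coverage_threshold` of the valid-water pixels unflagged and at least 4
#' valid values, compute the lake quantiles, assign the +-`tolerance`
#' bands, and accumulate the per-pixel relative frequency (percent) of
#' falling near the median, lower quartile and upper quartile. High
#' near-median frequency marks lake areas representative of the whole-lake
#' condition -- candidate monitoring sites.
#'
#' @param scenes list of scenes (with `$chl` and `$flags`)
#' @param valid_water_mask logical matrix from [build_valid_water_mask()]
#' @param tolerance band half-width, default 0.05
#' @param coverage_threshold minimum scene coverage, default 0.5
#' @param denominator see [accumulate_frequencies()]
#' @return a `composite_frequency` with extra fields `n_scenes_total`,
#'   `tolerance`, `coverage_threshold`, `transform`
#' @export
patchiness_composite <- function(scenes, valid_water_mask, tolerance = 0.05,
                                 coverage_threshold = 0.5,
                                 denominator = "per_pixel") {
  assignments <- list(); valids <- list()
  skipped <- 0L
  for (sc in scenes) {
    v <- valid_pixel_mask(sc$flags) & valid_water_mask
    cov <- scene_coverage(v, valid_water_mask)
    if (cov < coverage_threshold) { skipped <- skipped + 1L; next }
    vals <- sc$chl[v]
    vals <- vals[is.finite(vals)]
    if (length(vals) < 4L) {
      message("scene ", format_utc(sc$timestamp),
              " skipped: fewer than 4 valid values")
      skipped <- skipped + 1L
      next
    }
    qs <- lake_quantiles(vals)
    assignments[[length(assignments) + 1L]] <-
      assign_quantile_bands(sc$chl, v, qs, tolerance)
    valids[[length(valids) + 1L]] <- v
  }
  if (length(assignments) == 0L)
    stop("no scene meets the coverage rule (", skipped, " skipped)")
  out <- accumulate_frequencies(assignments, valids, denominator)
  out$n_scenes_total <- length(scenes)
  out$tolerance <- tolerance
  out$coverage_threshold <- coverage_threshold
  out$transform <- scenes[[1L]]$transform
  out
}
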