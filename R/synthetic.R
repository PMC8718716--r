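#' Generate a synthetic lake geometry
#'
#' Builds a connected, star-shaped lake on a north-up metre grid: the
#' outline radius is `radius * (1 + irregularity * sum_k a_k cos(k theta +
#' phi_k))` with seeded harmonic coefficients (`irregularity = 0` gives a
#' circle), the raster mask is the set of cells whose centre falls inside
#' the outline, and the bathymetry is a smooth bowl, deepest near the
#' centroid and 0 at the shore: `depth = max_depth * (1 - t^2)` with `t`
#' the relative radial position.
#'
#' @param rows,cols grid dimensions (>= 10)
#' @param cell_size pixel size in metres, default 60 (the working
#'   resolution after resampling multispectral bands to the coarsest band)
#' @param shape list with `radius` (m), `irregularity` (default 0),
#'   `n_harmonics` (default 3), `max_depth` (m, default 25)
#' @param seed integer seed for the harmonic coefficients
#' @return a [lake_geometry()]
#' @export
generate_lake_geometry <- function(rows, cols, cell_size = 60,
                                   shape = list(radius = 900),
                                   seed = 1L) {
  stopifnot(rows >= 10L, cols >= 10L, cell_size > 0)
  radius <- shape$radius
  if (is.null(radius) || radius <= 0) stop("shape$radius must be > 0")
  irr <- if (is.null(shape$irregularity)) 0 else shape$irregularity
  nh <- if (is.null(shape$n_harmonics)) 3L else shape$n_harmonics
  max_depth <- if (is.null(shape$max_depth)) 25 else shape$max_depth

  tr <- grid_transform(0, rows * cell_size, cell_size, rows, cols)
  cx <- cols * cell_size / 2
  cy <- rows * cell_size / 2

  coef <- with_seed(seed, list(a = stats::runif(nh, -1, 1),
                               phi = stats::runif(nh, 0, 2 * pi)))
  r_of_theta <- function(theta) {
    mod <- rep(0, length(theta))
    if (irr > 0 && nh > 0)
      for (k in seq_len(nh))
        mod <- mod + coef$a[k] * cos(k * theta + coef$phi[k]) / k
    radius * (1 + irr * mod)
  }

  theta <- seq(0, 2 * pi, length.out = 721L)[-721L]
  ring <- cbind(cx + r_of_theta(theta) * cos(theta),
                cy + r_of_theta(theta) * sin(theta))
  poly <- lake_polygon(ring)

  ctr <- grid_centers(tr)
  dx <- ctr$x - cx; dy <- ctr$y - cy
  d <- sqrt(dx^2 + dy^2)
  rt <- matrix(r_of_theta(atan2(as.vector(dy), as.vector(dx))), rows, cols)
  mask <- d <= rt

  bb <- which(mask, arr.ind = TRUE)
  if (sum(mask) < 25L || length(unique(bb[, 1L])) < 5L ||
      length(unique(bb[, 2L])) < 5L)
    stop("degenerate lake: smaller than 5x5 cells; the 120 m shoreline ",
         "buffer would erase it")

  t_rel <- pmin(1, d / rt)
  bathy <- ifelse(mask, max_depth * (1 - t_rel^2), 0)
  lake_geometry(poly, mask, bathy, tr)
}

#' Synthetic lake ground truth
#'
#' The stated world behind every synthetic scene: per-pixel true
#' chlorophyll is `base_chl * pattern * temporal_factor * noise`, where
#' `pattern` is a persistent multiplicative spatial field normalized to
#' mean 1 over the lake (the planted patchiness), `temporal_factor` is a
#' lake-wide per-scene multiplier, and `noise` is i.i.d. mean-1 lognormal
#' with coefficient of variation `noise_cv`.
#'
#' Pattern types:
#' \describe{
#'   \item{`"flat"`}{no patchiness (pattern identically 1).}
#'   \item{`"gradient"`}{a smooth cross-lake trend plus one low-frequency
#'     sinusoid; amplitude `pattern_amplitude`.}
#'   \item{`"terraced"`}{a terraced west-to-east front: an outer low
#'     terrace (~36% of lake pixels, values ramping 0.75-0.85), a central
#'     plateau (~28%, exactly at the lake-median pattern value) and a high
#'     terrace (~36%, 1.15-1.25). The wide exact-median plateau keeps the
#'     scene median pinned to the plateau under contiguous cloud loss while
#'     the >= 15% terrace separation makes near-median band membership
#'     statistically discriminable -- see the methods vignette.}
#' }
#'
#' @param geometry a [lake_geometry()]
#' @param base_chl lake-mean chlorophyll, mg m-3 (default 10, mesotrophic)
#' @param pattern one of `"gradient"`, `"terraced"`, `"flat"`
#' @param pattern_amplitude relative amplitude of the gradient pattern
#' @param noise_cv coefficient of variation of per-pixel scene noise (>= 0)
#' @param temporal_factors optional per-scene lake-wide multipliers; if
#'   `NULL`, [generate_scene_series()] draws seeded lognormal factors
#' @param seed integer seed for the pattern field
#' @return object of class `lake_truth`
#' @export
lake_truth <- function(geometry, base_chl = 10,
                       pattern = c("gradient", "terraced", "flat"),
                       pattern_amplitude = 0.3, noise_cv = 0.1,
                       temporal_factors = NULL, seed = 1L) {
  stopifnot(inherits(geometry, "lake_geometry"), base_chl > 0)
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  pattern <- match.arg(pattern)
  mask <- geometry$lake_mask
  tr <- geometry$transform
  pat <- matrix(1, nrow(mask), ncol(mask))

  if (pattern == "gradient") {
    ctr <- grid_centers(tr)
    xs <- ctr$x; ys <- ctr$y
    xr <- range(xs[mask]); yr <- range(ys[mask])
    u <- (xs - xr[1L]) / max(diff(xr), 1)
    v <- (ys - yr[1L]) / max(diff(yr), 1)
    ph <- with_seed(seed, stats::runif(2, 0, 2 * pi))
    field <- (u - 0.5) + 0.4 * sin(2 * pi * u + ph[1L]) * cos(pi * v + ph[2L])
    pat <- exp(pattern_amplitude * field)
  } else if (pattern == "terraced") {
    ctr <- grid_centers(tr)
    xs <- ctr$x[mask]
    lo_cut <- quantile_linear(xs, 0.36)
    hi_cut <- quantile_linear(xs, 0.64)
    xr <- range(xs)
    vals <- numeric(length(xs))
    lo <- xs <= lo_cut; hi <- xs > hi_cut; mid <- !lo & !hi
    # within-terrace ramps keep the outer terraces' own quantiles stable
    vals[lo] <- 0.75 + 0.10 * (xs[lo] - xr[1L]) / max(lo_cut - xr[1L], 1)
    vals[hi] <- 1.15 + 0.10 * (xs[hi] - hi_cut) / max(xr[2L] - hi_cut, 1)
    vals[mid] <- 1.0
    pat[mask] <- vals
  }
  # normalize to mean 1 over the lake (invariant: within 1%)
  pat <- pat / mean(pat[mask])

  structure(list(geometry = geometry, grid_shape = dim(mask),
                 cell_size = tr$cell, lake_mask = mask,
                 bathymetry = geometry$bathymetry,
                 base_chl = as.numeric(base_chl), pattern = pat,
                 pattern_type = pattern,
                 temporal_factors = temporal_factors,
                 noise_cv = as.numeric(noise_cv), seed = as.integer(seed)),
            class = "lake_truth")
}

#' Per-scene simulation parameters
#'
#' @param timestamp scene time (character ISO 8601 or `POSIXct` UTC)
#' @param temporal_factor lake-wide multiplier for this scene (default 1)
#' @param cloud_fraction fraction of the lake covered by the simulated
#'   cloud disc, in `[0, 1]`
#' @param flag_noise_rates named per-flag raise probabilities for negative
#'   flags other than the cloud family (e.g. `c(RTOSA_OOS = 0.01)`); a
#'   single unnamed number applies to all of them
#' @return object of class `scene_params`
#' @export
scene_params <- function(timestamp, temporal_factor = 1,
                         cloud_fraction = 0, flag_noise_rates = 0) {
  if (!(cloud_fraction >= 0 && cloud_fraction <= 1))
    stop("cloud_fraction must be in [0, 1]")
  stopifnot(temporal_factor > 0)
  if (is.character(timestamp)) timestamp <- parse_utc(timestamp)
  noisy <- setdiff(negative_flags(),
                   c("IDEPIX_CLOUD", "IDEPIX_CLOUD_BUFFER"))
  if (is.null(names(flag_noise_rates))) {
    stopifnot(length(flag_noise_rates) == 1L)
    flag_noise_rates <- structure(rep(as.numeric(flag_noise_rates),
                                      length(noisy)), names = noisy)
  } else {
    unknown <- setdiff(names(flag_noise_rates), noisy)
    if (length(unknown)) stop("unknown noisy flag(s): ",
                              paste(unknown, collapse = ", "))
    full <- structure(rep(0, length(noisy)), names = noisy)
    full[names(flag_noise_rates)] <- flag_noise_rates
    flag_noise_rates <- full
  }
  if (any(flag_noise_rates < 0 | flag_noise_rates > 1))
    stop("flag noise rates must be probabilities")
  structure(list(timestamp = timestamp, temporal_factor = temporal_factor,
                 cloud_fraction = cloud_fraction,
                 flag_noise_rates = flag_noise_rates),
            class = "scene_params")
}

# mean-1 lognormal deviates with coefficient of variation cv
rlnorm_mean1 <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate one synthetic scene
#'
#' Draws the per-pixel true chlorophyll field from the truth model, inverts
#' it to a consistent IOP triple ([iops_from_chl()] with a per-pixel seeded
#' pigment share in (0.5, 0.85)) so that the forward model with canonical
#' coefficients reproduces the truth to round-off, and simulates the flag
#' bitmask: `IDEPIX_WATER` on all lake pixels, `SHORE_SHALLOW_BUFFER` from
#' the geometry's valid-water mask (all lake pixels if none was built), one
#' contiguous random cloud disc of area about `cloud_fraction` times the
#' lake area with its 2-pixel dilation buffer, and independent per-pixel
#' noise on the remaining negative flags.
#'
#' @param truth a [lake_truth()]
#' @param params a [scene_params()]
#' @param seed integer seed for this scene's randomness
#' @return object of class `lake_scene`: `timestamp`, `chl`, `a_pig`,
#'   `a_det`, `a_cdom`, `flags`, `transform`, and the ground-truth field
#'   `true_chl`
#' @export
generate_scene <- function(truth, params, seed = 1L) {
  stopifnot(inherits(truth, "lake_truth"), inherits(params, "scene_params"))
  mask <- truth$lake_mask
  n <- sum(mask)
  dims <- dim(mask)

  draws <- with_seed(seed, {
    eps <- rlnorm_mean1(n, truth$noise_cv)
    f_pig <- stats::runif(n, 0.5, 0.85)
    f_det <- stats::runif(n, 0.3, 0.7)
    cloud_at <- sample.int(n, 1L)
    u_flags <- matrix(stats::runif(n * length(params$flag_noise_rates)),
                      nrow = n)
    list(eps = eps, f_pig = f_pig, f_det = f_det, cloud_at = cloud_at,
         u_flags = u_flags)
  })

  true_chl <- matrix(NA_real_, dims[1L], dims[2L])
  true_chl[mask] <- truth$base_chl * truth$pattern[mask] *
    params$temporal_factor * draws$eps

  iops <- iops_from_chl(true_chl[mask], calibration_coefficients(),
                        f_pig = draws$f_pig, f_det = draws$f_det)
  a_pig <- a_det <- a_cdom <- matrix(NA_real_, dims[1L], dims[2L])
  a_pig[mask] <- iops$a_pig
  a_det[mask] <- iops$a_det
  a_cdom[mask] <- iops$a_cdom
  chl <- matrix(NA_real_, dims[1L], dims[2L])
  chl[mask] <- chl_from_iops(iops$a_pig, iops$a_det, iops$a_cdom)

  layers <- list(IDEPIX_WATER = mask)
  vwm <- truth$geometry$valid_water_mask
  layers$SHORE_SHALLOW_BUFFER <- if (is.null(vwm)) mask else (vwm & mask)

  if (params$cloud_fraction > 0) {
    idx <- which(mask, arr.ind = TRUE)
    at <- idx[draws$cloud_at, ]
    r_cells <- sqrt(params$cloud_fraction * n / pi)
    ri <- matrix(seq_len(dims[1L]), dims[1L], dims[2L])
    ci <- matrix(seq_len(dims[2L]), dims[1L], dims[2L], byrow = TRUE)
    cloud <- (ri - at[1L])^2 + (ci - at[2L])^2 <= r_cells^2
    layers$IDEPIX_CLOUD <- cloud
    layers$IDEPIX_CLOUD_BUFFER <- apply_cloud_buffer(cloud, 2L) & !cloud
  }
  rates <- params$flag_noise_rates
  for (k in seq_along(rates)) {
    if (rates[k] > 0) {
      lay <- matrix(FALSE, dims[1L], dims[2L])
      lay[mask] <- draws$u_flags[, k] < rates[k]
      layers[[names(rates)[k]]] <- lay
    }
  }

  structure(list(timestamp = params$timestamp, chl = chl,
                 a_pig = a_pig, a_det = a_det, a_cdom = a_cdom,
                 flags = quality_flags(layers, dim = dims),
                 transform = truth$geometry$transform,
                 true_chl = true_chl),
            class = "lake_scene")
}

#' Generate a dated series of synthetic scenes
#'
#' Scenes at a fixed cadence (default 5 days, a Sentinel-2-like revisit).
#' Lake-wide temporal factors come from the truth object if set, otherwise
#' they are drawn once here as seeded lognormal multipliers (sdlog 0.3,
#' a realistic seasonal-scale spread).
#'
#' @param truth a [lake_truth()]
#' @param n_scenes number of scenes (>= 1)
#' @param start first scene time (ISO 8601)
#' @param cadence_days days between scenes
#' @param cloud_fraction per-scene cloud fraction (recycled)
#' @param flag_noise_rates see [scene_params()]
#' @param seed experiment seed; per-scene seeds are derived from it
#' @return list of [generate_scene()] results, time-ordered
#' @export
generate_scene_series <- function(truth, n_scenes, start = "2016-01-01",
                                  cadence_days = 5, cloud_fraction = 0,
                                  flag_noise_rates = 0, seed = 1L) {
  stopifnot(n_scenes >= 1L)
  tf <- truth$temporal_factors
  if (is.null(tf)) {
    tf <- with_seed(derive_seed(seed, "temporal"),
                    stats::rlnorm(n_scenes, meanlog = 0, sdlog = 0.3))
  }
  if (length(tf) < n_scenes)
    stop("temporal_factors shorter than the number of scenes")
  cf <- rep_len(cloud_fraction, n_scenes)
  t0 <- parse_utc(start)
  lapply(seq_len(n_scenes), function(k) {
    p <- scene_params(t0 + (k - 1) * cadence_days * 86400,
                      temporal_factor = tf[k], cloud_fraction = cf[k],
                      flag_noise_rates = flag_noise_rates)
    generate_scene(truth, p, seed = derive_seed(seed, paste0("scene", k)))
  })
}

#' Generate an in-situ survey from the ground truth
#'
#' One sample per station per scene: the true chlorophyll at the station's
#' pixel at the sampling instant, times mean-1 lognormal measurement noise.
#' Sampling instants are the scene times shifted by `time_offsets_h`
#' (hours, positive or negative, recycled over the scene x station grid),
#' emulating surveys taken near -- but not at -- the overpass.
#'
#' @param truth a [lake_truth()]
#' @param scenes list of [generate_scene()] results
#' @param stations data frame with columns `i`, `j` (grid row/col) and
#'   optionally `station_id`; all stations must be inside the lake mask
#' @param time_offsets_h sampling-time offsets in hours
#' @param measurement_cv coefficient of variation of measurement noise
#' @param source label, `"monitoring"` or `"other"`
#' @param lake_id lake label for the CSV schema
#' @param seed integer seed
#' @return data frame of class `insitu_samples` with columns `lake`,
#'   `station_id`, `i`, `j`, `x`, `y`, `datetime` (POSIXct UTC),
#'   `chl_mg_m3`, `source`
#' @export
generate_insitu_survey <- function(truth, scenes, stations,
                                   time_offsets_h = 0, measurement_cv = 0.1,
                                   source = "monitoring", lake_id = "synthetic",
                                   seed = 1L) {
  stopifnot(inherits(truth, "lake_truth"), length(scenes) >= 1L)
  if (measurement_cv < 0) stop("measurement_cv must be >= 0")
  stations <- as.data.frame(stations)
  if (!all(c("i", "j") %in% names(stations)))
    stop("stations need grid columns i, j")
  if (is.null(stations$station_id))
    stations$station_id <- sprintf("S%02d", seq_len(nrow(stations)))
  inside <- truth$lake_mask[cbind(stations$i, stations$j)]
  if (!all(inside))
    stop("station(s) outside the lake mask: ",
         paste(stations$station_id[!inside], collapse = ", "))
  if (!source %in% c("monitoring", "other"))
    stop('source must be "monitoring" or "other"')

  ns <- length(scenes); nst <- nrow(stations)
  grid <- expand.grid(scene = seq_len(ns), station = seq_len(nst))
  offs <- rep_len(time_offsets_h, nrow(grid))
  noise <- with_seed(seed, rlnorm_mean1(nrow(grid), measurement_cv))

  ctr <- cell_center(truth$geometry$transform,
                     stations$i[grid$station], stations$j[grid$station])
  truev <- vapply(seq_len(nrow(grid)), function(r) {
    sc <- scenes[[grid$scene[r]]]
    sc$true_chl[stations$i[grid$station[r]], stations$j[grid$station[r]]]
  }, numeric(1))
  times <- do.call(c, lapply(seq_len(nrow(grid)), function(r)
    scenes[[grid$scene[r]]]$timestamp + offs[r] * 3600))

  out <- data.frame(lake = lake_id,
                    station_id = stations$station_id[grid$station],
                    i = stations$i[grid$station], j = stations$j[grid$station],
                    x = ctr$x, y = ctr$y,
                    datetime = as.POSIXct(times, tz = "UTC"),
                    chl_mg_m3 = truev * noise,
                    source = source, stringsAsFactors = FALSE)
  class(out) <- c("insitu_samples", "data.frame")
  out
}

#' Generate Secchi-depth samples
#'
#' Positive depths drawn from a lognormal distribution; the default
#' (median 4 m, sdlog 0.4) spans the transparency range of clear to
#' mesotrophic lakes.
#'
#' @param n number of samples (>= 1)
#' @param meanlog,sdlog lognormal parameters of the depth, metres
#' @param seed integer seed
#' @return numeric vector of Secchi depths, metres
#' @export
generate_secchi_samples <- function(n, meanlog = log(4), sdlog = 0.4,
                                    seed = 1L) {
  if (n < 1L) stop("n must be >= 1")
  with_seed(seed, stats::rlnorm(n, meanlog = meanlog, sdlog = sdlog))
}
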