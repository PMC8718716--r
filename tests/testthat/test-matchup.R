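test_that("time pairing is inclusive at 24 h and multiplies counts", {
  t0 <- parse_utc("2017-03-01T10:00:00Z")
  scenes_t <- t0 + c(0, 5, 10, 15) * 86400
  s <- data.frame(datetime = c(t0 + 23.9 * 3600, t0 + 24.1 * 3600))
  p <- pair_by_time(s, scenes_t, 24)
  expect_identical(p$sample_idx, 1L)        # 23.9 h in, 24.1 h out
  expect_equal(p$dt_hours, 23.9)
  expect_identical(nrow(pair_by_time(s, as.POSIXct(character(0)))), 0L)
  # 3 samples x 4 scenes all within the window
  s3 <- data.frame(datetime = rep(t0, 3))
  sc4 <- t0 + c(-20, -2, 3, 20) * 3600
  expect_identical(nrow(pair_by_time(s3, sc4, 24)), 12L)
  # exact boundary is inclusive
  expect_identical(nrow(pair_by_time(data.frame(datetime = t0 + 24 * 3600),
                                     t0, 24)), 1L)
})

test_that("macropixel extraction clips at raster edges and centres by the affine transform", {
  tr <- grid_transform(0, 600, 60, 10, 10)
  sc <- list(chl = matrix(5, 10, 10), transform = tr)
  vm <- matrix(TRUE, 10, 10)
  corner <- extract_macropixel(sc, x = 30, y = 570, vm)   # cell (1,1)
  expect_identical(sum(!is.na(corner$values)), 4L)
  expect_lte(sum(corner$valid), 4L)
  mid <- extract_macropixel(sc, x = 310, y = 290, vm)
  # independent coordinate oracle: col = floor(x/60)+1, row = floor((600-y)/60)+1
  expect_identical(mid$center,
                   c(i = as.integer(floor((600 - 290) / 60) + 1),
                     j = as.integer(floor(310 / 60) + 1)))
  expect_identical(sum(mid$valid), 9L)
  expect_true(all(mid$values == 5))
  expect_error(extract_macropixel(sc, x = -100, y = 290, vm), "outside")
})

test_that("homogeneity ratio matches the hand-computed fixture and is scale-invariant", {
  all_equal <- assess_homogeneity(rep(3.3, 9))
  expect_identical(all_equal$ratio, 0)
  expect_true(all_equal$passed)
  v <- c(rep(1, 8), 2)
  got <- assess_homogeneity(v)
  sd_hand <- sqrt(mean((v - mean(v))^2))     # population form
  expect_equal(got$ratio, sd_hand / 1)       # median = 1
  expect_false(got$passed)                   # 0.314 >= 0.20
  for (c_scale in c(0.01, 3.7, 1000)) {
    expect_equal(assess_homogeneity(c_scale * v)$ratio, got$ratio,
                 tolerance = 1e-12)
  }
  neg <- assess_homogeneity(c(-2, -1, 0))
  expect_false(neg$passed)
  expect_identical(neg$reason, "nonpositive_median")
})

test_that("a constant, fully valid macropixel passes with its value; 5 valid pixels are rejected", {
  w <- small_world(n_scenes = 1L, pattern = "flat", noise_cv = 0,
                   temporal_factors = 1)
  sc <- w$scenes[[1L]]
  ctr <- cell_center(sc$transform, 12, 12)
  smp <- data.frame(x = ctr$x, y = ctr$y, datetime = sc$timestamp,
                    chl_mg_m3 = 10, station_id = "S1")
  rec <- build_matchups(smp, list(sc))
  expect_true(rec$passed)
  expect_identical(rec$n_valid, 9L)
  expect_equal(rec$satellite_chl, 10, tolerance = 1e-9)

  # knock the macropixel down to 5 valid cells via cloud flags
  cloud <- matrix(FALSE, 24, 24); cloud[11:12, 11:12] <- TRUE
  sc2 <- sc
  sc2$flags <- quality_flags(list(IDEPIX_WATER = w$truth$lake_mask,
                                  SHORE_SHALLOW_BUFFER = w$truth$lake_mask,
                                  IDEPIX_CLOUD = cloud))
  rec2 <- build_matchups(smp, list(sc2))
  expect_false(rec2$passed)
  expect_identical(rec2$n_valid, 5L)
  expect_identical(rec2$rejection_reason, "insufficient_valid")
})

test_that("noiseless co-located, co-timed samples reproduce the in-situ value exactly", {
  w <- small_world(n_scenes = 3L, pattern = "gradient", noise_cv = 0)
  st <- data.frame(i = c(12, 13), j = c(12, 10))
  smp <- generate_insitu_survey(w$truth, w$scenes, st, time_offsets_h = 0,
                                measurement_cv = 0)
  rec <- build_matchups(smp, w$scenes)
  # keep co-timed pairs only (each sample also pairs with neighbour scenes)
  co <- rec[rec$dt_hours == 0, ]
  expect_true(all(co$passed))
  # macropixel mean over a smooth gradient is within the homogeneity spread
  expect_true(all(abs(co$satellite_chl / co$chl_insitu - 1) < 0.2))
  # the centre-pixel value itself is exact: re-extract and compare
  vm <- valid_pixel_mask(w$scenes[[1]]$flags)
  mp <- extract_macropixel(w$scenes[[1]], smp$x[1], smp$y[1], vm)
  expect_equal(mp$values[5], smp$chl_mg_m3[1], tolerance = 1e-9)
})

test_that("samples offset by +-30 h produce no match-ups under the 24 h rule", {
  w <- small_world(n_scenes = 2L)
  # scene cadence is 5 days, so +-30 h falls outside every window
  smp <- generate_insitu_survey(w$truth, w$scenes, data.frame(i = 12, j = 12),
                                time_offsets_h = c(30, -30))
  rec <- build_matchups(smp, w$scenes)
  expect_identical(nrow(rec), 0L)
})

test_that("build_matchups agrees with the straight-line oracle on a 500-candidate fixture", {
  set.seed(77)
  w <- small_world(n_scenes = 10L, pattern = "gradient", noise_cv = 0.25,
                   cloud_fraction = 0.25, seed = 77)
  mask_idx <- which(w$truth$lake_mask, arr.ind = TRUE)
  pick <- mask_idx[sample.int(nrow(mask_idx), 50, replace = TRUE), ]
  ctr <- cell_center(w$geometry$transform, pick[, 1], pick[, 2])
  base_t <- vapply(w$scenes, function(s) as.numeric(s$timestamp), numeric(1))
  smp <- data.frame(
    x = ctr$x + stats::runif(50, -25, 25),     # off-centre but same cell
    y = ctr$y + stats::runif(50, -25, 25),
    datetime = as.POSIXct(sample(base_t, 50, replace = TRUE) +
                            stats::runif(50, -30, 30) * 3600,
                          tz = "UTC", origin = "1970-01-01"),
    chl_mg_m3 = stats::rlnorm(50, log(10), 0.5),
    station_id = sprintf("S%02d", 1:50))
  rec <- build_matchups(smp, w$scenes)
  vms <- lapply(w$scenes, function(s) valid_pixel_mask(s$flags))
  orc <- oracle_matchups(smp, w$scenes, vms)
  expect_identical(nrow(rec), nrow(orc))
  key <- function(d) order(d$sample_idx, d$scene_idx)
  rec <- rec[key(rec), ]; orc <- orc[key(orc), ]
  expect_identical(rec$passed, orc$passed)
  expect_identical(rec$n_valid, orc$n_valid)
  expect_identical(is.na(rec$rejection_reason), is.na(orc$reason))
  expect_identical(rec$rejection_reason[!rec$passed], orc$reason[!orc$passed])
  expect_equal(rec$satellite_chl, orc$satellite_chl, tolerance = 1e-12)
})

test_that("QC results are invariant to sample and scene ordering", {
  w <- small_world(n_scenes = 4L, pattern = "gradient", noise_cv = 0.1,
                   cloud_fraction = 0.2, seed = 13)
  smp <- generate_insitu_survey(w$truth, w$scenes,
                                data.frame(i = c(12, 10, 14), j = c(12, 13, 9)),
                                time_offsets_h = c(-5, 3), measurement_cv = 0.1)
  rec <- build_matchups(smp, w$scenes)
  perm_s <- sample(nrow(smp)); perm_c <- sample(length(w$scenes))
  rec_p <- build_matchups(smp[perm_s, ], w$scenes[perm_c])
  # map permuted indices back and compare as sets
  rec_p$sample_idx <- perm_s[rec_p$sample_idx]
  rec_p$scene_idx <- perm_c[rec_p$scene_idx]
  o1 <- rec[order(rec$sample_idx, rec$scene_idx), ]
  o2 <- rec_p[order(rec_p$sample_idx, rec_p$scene_idx), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
})
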