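test_that("scene coverage counts valid-water pixels and errors on an empty mask", {
  vwm <- matrix(c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE), 2, 3)
  full <- matrix(TRUE, 2, 3)
  expect_identical(scene_coverage(full, vwm), 1)
  half <- matrix(c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE), 2, 3)
  expect_identical(scene_coverage(half, vwm), 0.5)
  expect_error(scene_coverage(full, matrix(FALSE, 2, 3)), "empty")
})

test_that("cloud-disc coverage matches a direct pixel count", {
  w <- small_world(n_scenes = 1L, cloud_fraction = 0.3, seed = 21)
  sc <- w$scenes[[1L]]
  vwm <- w$truth$lake_mask
  v <- valid_pixel_mask(sc$flags) & vwm
  expect_identical(scene_coverage(v, vwm), sum(v & vwm) / sum(vwm))
})

test_that("lake quantiles follow the linear-interpolation rule", {
  q <- lake_quantiles(c(1, 2, 3, 4, 5))
  expect_identical(c(q$q25, q$q50, q$q75), c(2, 3, 4))
  qc <- lake_quantiles(rep(7.5, 20))
  expect_identical(c(qc$q25, qc$q50, qc$q75), rep(7.5, 3))
  expect_error(lake_quantiles(c(1, 2, 3)), "fewer than 4")
})

test_that("band assignment: constant field, inclusive bounds, 4-pixel manual enumeration", {
  val <- matrix(5, 3, 3); ok <- matrix(TRUE, 3, 3)
  qs <- lake_quantiles(rep(5, 9))
  b <- assign_quantile_bands(val, ok, qs)
  expect_true(all(b$band_q50 & b$band_q25 & b$band_q75))

  # value exactly at 1.05 * q50 is assigned (inclusive upper bound)
  v2 <- matrix(c(10, 10, 10, 10.5), 2, 2)
  qs2 <- structure(list(q25 = 10, q50 = 10, q75 = 10, n_valid = 4),
                   class = "quantile_summary")
  b2 <- assign_quantile_bands(v2, matrix(TRUE, 2, 2), qs2)
  expect_true(b2$band_q50[2, 2])
  expect_false(assign_quantile_bands(v2 + c(0, 0, 0, 0.001),
                                     matrix(TRUE, 2, 2), qs2)$band_q50[2, 2])

  # full manual enumeration on {1,2,3,4}: q25 = 1.75, q50 = 2.5, q75 = 3.25;
  # +-5% intervals [1.6625,1.8375], [2.375,2.625], [3.0875,3.4125] contain
  # none of the four values
  v4 <- matrix(c(1, 2, 3, 4), 2, 2)
  qs4 <- lake_quantiles(c(1, 2, 3, 4))
  expect_identical(c(qs4$q25, qs4$q50, qs4$q75), c(1.75, 2.5, 3.25))
  b4 <- assign_quantile_bands(v4, matrix(TRUE, 2, 2), qs4)
  expect_false(any(b4$band_q50 | b4$band_q25 | b4$band_q75))
})

test_that("frequency accumulation matches the counting oracle", {
  dims <- c(1, 1)
  mk <- function(in_band, valid) {
    list(assign = list(band_q50 = matrix(in_band, 1, 1),
                       band_q25 = matrix(FALSE, 1, 1),
                       band_q75 = matrix(FALSE, 1, 1)),
         valid = matrix(valid, 1, 1))
  }
  scenes <- c(lapply(1:4, function(k) mk(TRUE, TRUE)),
              lapply(1:6, function(k) mk(FALSE, TRUE)))
  comp <- accumulate_frequencies(lapply(scenes, `[[`, "assign"),
                                 lapply(scenes, `[[`, "valid"))
  expect_identical(comp$band_q50[1, 1], 40)     # 4 of 10 valid scenes
  # never-valid pixel is NA; all-scenes denominator divides by 10 regardless
  scenes2 <- c(scenes, lapply(1:2, function(k) mk(FALSE, FALSE)))
  comp2 <- accumulate_frequencies(lapply(scenes2, `[[`, "assign"),
                                  lapply(scenes2, `[[`, "valid"))
  expect_identical(comp2$band_q50[1, 1], 40)    # per-pixel denominator still 10
  comp3 <- accumulate_frequencies(lapply(scenes2, `[[`, "assign"),
                                  lapply(scenes2, `[[`, "valid"),
                                  denominator = "all_scenes")
  expect_equal(comp3$band_q50[1, 1], 100 * 4 / 12)
})

test_that("constant fields give 100% in all bands; frequencies live in [0, 100]", {
  w <- small_world(n_scenes = 6L, pattern = "flat", noise_cv = 0)
  vwm <- build_valid_water_mask(w$geometry, rep(1, 5), 120)
  comp <- patchiness_composite(w$scenes, vwm)
  for (b in c("band_q50", "band_q25", "band_q75")) {
    vals <- comp[[b]][vwm]
    expect_true(all(vals == 100))
    expect_true(all(comp[[b]] >= 0 & comp[[b]] <= 100, na.rm = TRUE))
  }
  expect_true(all(is.na(comp$band_q50[!vwm])))
})

test_that("band frequencies are scale-invariant and permutation-invariant", {
  w <- small_world(n_scenes = 8L, pattern = "gradient", noise_cv = 0.15,
                   cloud_fraction = 0.2, seed = 5)
  vwm <- build_valid_water_mask(w$geometry, rep(1, 5), 120)
  comp <- patchiness_composite(w$scenes, vwm)
  scaled <- lapply(w$scenes, function(s) { s$chl <- s$chl * 3.7; s })
  comp_s <- patchiness_composite(scaled, vwm)
  for (b in c("band_q50", "band_q25", "band_q75"))
    expect_identical(comp[[b]], comp_s[[b]])
  set.seed(2)
  comp_p <- patchiness_composite(w$scenes[sample(length(w$scenes))], vwm)
  for (b in c("band_q50", "band_q25", "band_q75"))
    expect_identical(comp[[b]], comp_p[[b]])
})

test_that("scenes failing the coverage rule are excluded (inclusive threshold)", {
  w <- small_world(n_scenes = 4L, pattern = "flat", noise_cv = 0)
  vwm <- build_valid_water_mask(w$geometry, rep(1, 5), 120)
  # scene 1: flag exactly half of the valid-water pixels as cloud
  idx <- which(vwm)
  cloud <- matrix(FALSE, nrow(vwm), ncol(vwm))
  cloud[idx[seq_len(ceiling(length(idx) / 2))]] <- TRUE
  s1 <- w$scenes[[1L]]
  s1$flags <- quality_flags(list(IDEPIX_WATER = w$truth$lake_mask,
                                 SHORE_SHALLOW_BUFFER = w$truth$lake_mask,
                                 IDEPIX_CLOUD = cloud))
  v1 <- valid_pixel_mask(s1$flags) & vwm
  cov <- scene_coverage(v1, vwm)
  comp <- patchiness_composite(c(list(s1), w$scenes[-1L]), vwm)
  expect_identical(comp$n_scenes, if (cov >= 0.5) 4L else 3L)
  # a scene with every valid-water pixel clouded can never participate
  cloud_all <- matrix(FALSE, nrow(vwm), ncol(vwm)); cloud_all[vwm] <- TRUE
  s_all <- s1
  s_all$flags <- quality_flags(list(IDEPIX_WATER = w$truth$lake_mask,
                                    SHORE_SHALLOW_BUFFER = w$truth$lake_mask,
                                    IDEPIX_CLOUD = cloud_all))
  comp2 <- patchiness_composite(c(list(s_all), w$scenes[-1L]), vwm)
  expect_identical(comp2$n_scenes, 3L)
})
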