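test_that("circular lake mask matches the point-in-circle oracle (~pi 15^2 cells)", {
  geom <- circle_geometry()          # radius 900 m on 60 m cells: 15 cells
  ctr <- lakechl:::grid_centers(geom$transform)
  cx <- 50 * 60 / 2; cy <- 50 * 60 / 2
  oracle <- (ctr$x - cx)^2 + (ctr$y - cy)^2 <= 900^2
  expect_identical(geom$lake_mask, oracle)
  expect_lt(abs(sum(oracle) - pi * 15^2), 0.03 * pi * 15^2)
})

test_that("generators are bit-reproducible under a fixed seed", {
  g1 <- generate_lake_geometry(30, 30, 60, list(radius = 700, irregularity = 0.15),
                               seed = 9L)
  g2 <- generate_lake_geometry(30, 30, 60, list(radius = 700, irregularity = 0.15),
                               seed = 9L)
  expect_identical(g1, g2)
  t1 <- lake_truth(g1, pattern = "gradient", seed = 9L)
  s1 <- generate_scene(t1, scene_params("2016-05-01", cloud_fraction = 0.2,
                                        flag_noise_rates = 0.01), seed = 3L)
  s2 <- generate_scene(t1, scene_params("2016-05-01", cloud_fraction = 0.2,
                                        flag_noise_rates = 0.01), seed = 3L)
  expect_identical(s1, s2)
  expect_identical(generate_secchi_samples(50, seed = 5L),
                   generate_secchi_samples(50, seed = 5L))
})

test_that("degenerate lakes (smaller than 5x5 cells) are rejected", {
  expect_error(generate_lake_geometry(20, 20, 60, list(radius = 100)),
               "degenerate")
})

test_that("clean scenes raise no negative flags; noiseless limit is exact", {
  w <- small_world(n_scenes = 1L, pattern = "gradient", noise_cv = 0,
                   temporal_factors = 1)
  sc <- w$scenes[[1L]]
  neg <- Reduce(`|`, lapply(negative_flags(), function(nm)
    flag_layer(sc$flags, nm)))
  expect_false(any(neg))
  mask <- w$truth$lake_mask
  expect_identical(sc$true_chl[mask], (10 * w$truth$pattern)[mask])
})

test_that("IOP inversion round-trips through the forward model to 1e-9 relative", {
  w <- small_world(n_scenes = 3L, pattern = "gradient", noise_cv = 0.2,
                   cloud_fraction = 0.1)
  for (sc in w$scenes) {
    mask <- w$truth$lake_mask
    back <- chl_from_iops(sc$a_pig[mask], sc$a_det[mask], sc$a_cdom[mask])
    expect_lt(max(abs(back / sc$true_chl[mask] - 1)), 1e-9)
    expect_true(all(sc$a_pig[mask] >= 0 & sc$a_det[mask] >= 0 &
                      sc$a_cdom[mask] >= 0))
  }
})

test_that("cloud disc area tracks cloud_fraction and the water flag covers the lake", {
  w <- small_world(n_scenes = 1L, cloud_fraction = 0.3)
  sc <- w$scenes[[1L]]
  expect_identical(flag_layer(sc$flags, "IDEPIX_WATER"), w$truth$lake_mask)
  cloud <- flag_layer(sc$flags, "IDEPIX_CLOUD")
  expect_gt(sum(cloud & w$truth$lake_mask), 0)
  buf <- flag_layer(sc$flags, "IDEPIX_CLOUD_BUFFER")
  expect_identical(buf, apply_cloud_buffer(cloud, 2L) & !cloud)
  expect_error(scene_params("2016-01-01", cloud_fraction = 1.4), "cloud_fraction")
  expect_error(lake_truth(w$geometry, noise_cv = -0.1), "noise_cv")
})

test_that("pattern fields have lake-mean within 1% of 1 and bathymetry is a valid bowl", {
  for (p in c("flat", "gradient", "terraced")) {
    w <- small_world(n_scenes = 1L, pattern = p)
    mask <- w$truth$lake_mask
    expect_lt(abs(mean(w$truth$pattern[mask]) - 1), 0.01)
  }
  geom <- circle_geometry()
  expect_true(all(geom$bathymetry >= 0))
  expect_true(all(geom$bathymetry[!geom$lake_mask] == 0))
  expect_gt(geom$bathymetry[25, 25], max(geom$bathymetry[geom$lake_mask] * 0.9))
})

test_that("in-situ survey: noiseless co-located samples equal the true field; counts multiply", {
  w <- small_world(n_scenes = 4L, pattern = "gradient", noise_cv = 0.1)
  st <- data.frame(i = c(12, 10), j = c(12, 14))
  smp <- generate_insitu_survey(w$truth, w$scenes, st, time_offsets_h = 0,
                                measurement_cv = 0, seed = 2L)
  expect_identical(nrow(smp), 4L * 2L)   # n scenes x m stations
  for (r in seq_len(nrow(smp))) {
    k <- which(vapply(w$scenes, function(s)
      identical(s$timestamp, smp$datetime[r]), logical(1)))
    expect_identical(smp$chl_mg_m3[r],
                     w$scenes[[k]]$true_chl[smp$i[r], smp$j[r]])
  }
  expect_error(generate_insitu_survey(w$truth, w$scenes,
                                      data.frame(i = 1, j = 1)),
               "outside the lake mask")
})

test_that("secchi samples follow the stated lognormal and degenerate cases behave", {
  expect_identical(generate_secchi_samples(5, meanlog = log(4), sdlog = 0),
                   rep(4, 5))
  s <- generate_secchi_samples(1000, meanlog = log(4), sdlog = 0.4, seed = 3L)
  expect_true(all(s > 0))
  analytic <- stats::qlnorm(0.95, log(4), 0.4)
  expect_lt(abs(quantile_linear(s, 0.95) / analytic - 1), 0.05)
  expect_error(generate_secchi_samples(0), "n must be >= 1")
})

test_that("averaging many cloud-free scenes recovers the planted pattern", {
  n <- 400L  # >=200; at 400 the 3*cv/sqrt(200) bound is ~4 sigma per pixel
  w <- small_world(n_scenes = n, pattern = "gradient", noise_cv = 0.1,
                   rows = 20L, cols = 20L, radius = 500,
                   temporal_factors = rep(1, n), seed = 4L)
  mask <- w$truth$lake_mask
  acc <- Reduce(`+`, lapply(w$scenes, function(s) s$true_chl[mask]))
  est <- acc / n / 10                       # base_chl = 10
  rel <- abs(est / w$truth$pattern[mask] - 1)
  expect_lt(max(rel), 3 * 0.1 / sqrt(200))
})
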