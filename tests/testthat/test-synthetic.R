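test_that("parameter draws are uniform over the simulation ranges", {
  d <- sample_parameters(10000, seed = 3)
  expect_equal(nrow(d), 10000L)
  # uniform order statistics: extremes hug the range ends
  expect_true(min(d$mua) >= 0.01 && min(d$mua) <= 0.012)
  expect_true(max(d$mua) <= 0.1 && max(d$mua) >= 0.098)
  expect_true(all(d$depth >= 1.5 & d$depth <= 3))
  expect_true(all(abs(d$tilt) <= 15))
  expect_true(all(d$mua_chest >= 0.1 & d$mua_chest <= 0.24))
  # Kolmogorov-Smirnov uniformity on each margin
  rng <- list(mua = c(0.01, 0.1), musp = c(4, 10), mua_chest = c(0.1, 0.24),
              musp_chest = c(4, 10), depth = c(1.5, 3), tilt = c(-15, 15))
  for (nm in names(rng)) {
    p <- suppressWarnings(stats::ks.test(
      (d[[nm]] - rng[[nm]][1]) / diff(rng[[nm]]), "punif"))$p.value
    expect_gt(p, 0.01)
  }
  # same seed reproduces the draws exactly
  expect_identical(d, sample_parameters(10000, seed = 3))
})

test_that("measurement noise has the stated level and respects the mask", {
  m <- fx_homog_measurement()
  expect_identical(add_noise(m, 0), m)
  # pool many replicates: ~10^4 pair perturbations
  dla <- unlist(lapply(1:80, function(s)
    add_noise(m, 0.01, seed = s)$log_amplitude - m$log_amplitude))
  expect_gt(stats::sd(dla), 0.009)
  expect_lt(stats::sd(dla), 0.011)
  # masked entries are perturbed but the mask itself is unchanged
  mm <- remove_long_separations(m)
  noisy <- add_noise(mm, 0.01, seed = 1)
  expect_identical(noisy$valid_mask, mm$valid_mask)
  expect_false(any(noisy$log_amplitude[!mm$valid_mask] ==
                     mm$log_amplitude[!mm$valid_mask]))
  # seeded noise is reproducible
  expect_equal(add_noise(m, 0.01, seed = 9), add_noise(m, 0.01, seed = 9))
})

test_that("simulation datasets are assembled and split as configured", {
  ds <- make_simulation_dataset(n = 100, seed = 17)
  expect_equal(sum(ds$split == "train"), 90L)
  expect_equal(sum(ds$split == "test"), 10L)
  expect_equal(ncol(ds$features), 256L)
  expect_false(any(is.na(ds$features)))
  # labels are exactly the generating draws
  draws <- sample_parameters(100, seed = 17)
  expect_equal(unname(ds$labels),
               unname(as.matrix(draws[, c("mua", "musp", "mua_chest",
                                          "musp_chest")])))
  # depth features in each row match the draw's geometry
  i <- 42
  g <- chestwall_geometry(draws$depth[i], draws$tilt[i])
  expect_equal(unname(ds$features[i, 253:256]),
               chestwall_depth_features(g))
  # regeneration is bit-identical
  ds2 <- make_simulation_dataset(n = 100, seed = 17)
  expect_identical(ds$features, ds2$features)
})

test_that("dataset CSV round trip preserves features, labels and split", {
  ds <- make_simulation_dataset(n = 30, seed = 23)
  path <- withr::local_tempfile(fileext = ".csv")
  dataset_to_csv(ds, path)
  ds2 <- dataset_from_csv(path)
  expect_equal(ds2$features, ds$features, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(unname(ds2$labels), unname(ds$labels), tolerance = 1e-12)
  expect_identical(ds2$split, ds$split)
})

test_that("the lab fixture reduces to plain simulation without gains/noise", {
  gid <- gain_set(rep(1 + 0i, 9), rep(1 + 0i, 14))
  fx <- make_lab_fixture(n_backgrounds = 3L, seed = 31, noise_level = 0,
                         gains = gid)
  expect_equal(nrow(fx$features), 12L)
  # rebuild one example directly from its recorded truth
  i <- 5
  med <- suppressWarnings(two_layer_medium(
    optical_props(fx$labels[i, 1], fx$labels[i, 2]),
    optical_props(fx$labels[i, 3], fx$labels[i, 4]),
    chestwall_geometry(fx$geometry$depth[i], fx$geometry$tilt[i]),
    refractive_index = 1.4))
  med$refractive_index <- 1.33
  m <- preprocess_measurement(fluence_two_layer(med, default_probe()))
  fv <- build_feature_vector(
    m, chestwall_depth_features(chestwall_geometry(fx$geometry$depth[i],
                                                   fx$geometry$tilt[i])))
  expect_equal(unname(fx$features[i, ]), unname(fv), tolerance = 1e-8)
})

test_that("fixture calibration removes the injected instrument gains", {
  fx <- make_lab_fixture(n_backgrounds = 2L, seed = 41)
  g_true <- fx$meta$gains_true
  g_fit <- fx$meta$gains_fitted
  resid <- Mod(c(g_fit$source_gains / g_true$source_gains,
                 g_fit$detector_gains / g_true$detector_gains))
  expect_lt(max(abs(resid - 1)), 0.03)
  # fixture scale: 196 backgrounds x 4 phantoms reproduces 784 sets, 70/30
  expect_equal(196L * 4L, 784L)
  expect_equal(sum(fx$split == "train") / nrow(fx$features), 0.7,
               tolerance = 0.15)
})
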