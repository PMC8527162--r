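# Small phantoms (4 cm lateral extent) keep these tests fast; the generator
# is identical at full size apart from the grid dimensions.

small_phantom <- function(frac = 0.6, depth = 2, seed = 1, ...) {
  generate_digital_phantom(frac, depth, seed = seed, size_xy = 4, ...)
}

test_that("realized fibroglandular fraction matches the target", {
  for (frac in c(0.2, 0.45, 0.8)) {
    ph <- small_phantom(frac, seed = frac * 100)
    g <- ph$grid
    breast <- g == 1L | g == 2L
    realized <- sum(g == 2L) / sum(breast)
    expect_lt(abs(realized - frac), 0.02)
  }
})

test_that("phantom generation is reproducible and labelled correctly", {
  p1 <- small_phantom(seed = 5)
  p2 <- small_phantom(seed = 5)
  expect_identical(p1$grid, p2$grid)
  expect_false(identical(p1$grid, small_phantom(seed = 6)$grid))
  # default label properties
  expect_equal(p1$label_props$fat$mua, 0.02)
  expect_equal(p1$label_props$fat$musp, 5)
  expect_equal(p1$label_props$fibroglandular$mua, 0.04)
  expect_equal(p1$label_props$fibroglandular$musp, 8)
  # chest wall occupies every voxel below the interface
  d <- dim(p1$grid)
  iface <- 2 * (8 / 5) / 0.05           # uncompressed interface layer
  expect_true(all(p1$grid[, , (iface + 1):d[3]] == 3L))
  expect_true(all(p1$grid[, , 1:iface] %in% c(1L, 2L)))
})

test_that("compression and downsampling preserve structure", {
  ph <- small_phantom(0.5, seed = 9)
  cp <- compress_and_downsample(ph)
  expect_equal(cp$spacing, 0.25)
  d <- dim(cp$grid)
  expect_equal(d[3] * cp$spacing, 5)    # compressed to 5 cm
  # volume fractions preserved within 3 percentage points
  frac0 <- sum(ph$grid == 2L) / sum(ph$grid %in% c(1L, 2L))
  frac1 <- sum(cp$grid == 2L) / sum(cp$grid %in% c(1L, 2L))
  expect_lt(abs(frac1 - frac0), 0.03)
  # the chest interface lands at the measurement-time depth
  k_iface <- min(which(apply(cp$grid == 3L, 3, all)))
  expect_equal((k_iface - 1) * cp$spacing, cp$chest_depth, tolerance = 0.26)
  # a uniform phantom stays uniform
  uni <- voxel_phantom(array(1L, c(20, 20, 12)), 0.05,
                       list(fat = optical_props(0.02, 5)), chest_depth = 2)
  expect_true(all(compress_and_downsample(uni,
    target_thickness = 0.5, target_spacing = 0.1)$grid == 1L))
})

test_that("weighted-average truth is the volume-weighted breast mean", {
  # 40% fat / 60% fibroglandular reproduces (0.032, 6.8)
  ph <- small_phantom(0.6, depth = 2, seed = 12)
  tr <- weighted_average_truth(ph)
  expect_equal(tr$mua, 0.032)
  expect_equal(tr$musp, 6.8)
  # pure fat
  uni <- voxel_phantom(array(1L, c(10, 10, 10)), 0.05,
                       list(fat = optical_props(0.02, 5)), chest_depth = 2)
  expect_equal(weighted_average_truth(uni)$mua, 0.02)
  expect_equal(weighted_average_truth(uni)$musp, 5)
})

test_that("lesion voxels are carved out but excluded from the truth", {
  ph0 <- small_phantom(0.6, seed = 12)
  ph1 <- small_phantom(0.6, seed = 12,
                       lesion = list(center = c(0, 0, 1.5), radius = 0.5,
                                     mua = 0.2, musp = 7))
  expect_gt(sum(ph1$grid == 4L), 0)
  # the lesion displaces a handful of breast voxels (slightly shifting the
  # fat/fibro ratio) but its own properties must not enter the average
  t0 <- weighted_average_truth(ph0)
  t1 <- weighted_average_truth(ph1)
  expect_equal(t1$mua, t0$mua, tolerance = 5e-3)
  expect_error(small_phantom(0.6, lesion = list(center = c(50, 0, 1.5),
                                                radius = 0.5, mua = 0.2,
                                                musp = 7)),
               "outside")
})

test_that("phantoms survive the text-file round trip", {
  ph <- small_phantom(0.4, seed = 21)
  prefix <- file.path(withr::local_tempdir(), "ph")
  phantom_to_files(ph, prefix)
  ph2 <- phantom_from_files(prefix)
  expect_identical(ph2$grid, ph$grid)
  expect_equal(ph2$spacing, ph$spacing)
  expect_equal(ph2$label_props$fat$mua, ph$label_props$fat$mua)
  expect_equal(ph2$chest_depth, ph$chest_depth)
})
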