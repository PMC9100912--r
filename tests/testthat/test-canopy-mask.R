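make_two_band_cube <- function(Ra, Rb) {
  arr <- array(c(Ra, Rb), dim = c(nrow(Ra), ncol(Ra), 2))
  spectral_cube(arr, c(600, 800))
}

test_that("normalized difference images follow the two-band formula", {
  Ra <- matrix(0.5, 3, 3); Rb <- matrix(0.1, 3, 3)
  img <- normalized_difference_image(make_two_band_cube(Ra, Rb), 600, 800)
  expect_equal(img$values, matrix((0.5 - 0.1) / (0.5 + 0.1), 3, 3))
  expect_equal(unname(img$values[1, 1]), 0.666667, tolerance = 1e-6)

  # identical bands give zeros; zero denominator gives NA
  img0 <- normalized_difference_image(make_two_band_cube(Ra, Ra), 600, 800)
  expect_true(all(img0$values == 0))
  Rz <- matrix(0, 3, 3)
  imgz <- normalized_difference_image(make_two_band_cube(Rz, Rz), 600, 800)
  expect_true(all(is.na(imgz$values)))
})

test_that("requested wavelengths snap to the nearest band and are recorded", {
  cube <- random_cube(2, 2, default_grid)
  img <- normalized_difference_image(cube, 663, 781)
  expect_equal(img$source_wavelengths, c(662, 782))
  expect_error(normalized_difference_image(cube, 440, 782), "wavelength")
})

test_that("NDCSI separates sunlit canopy from shadow and stays in [0, 1]", {
  sc <- generate_scene(scene_config(seed = 21))
  img <- ndcsi_image(sc$cube)
  v <- img$values
  expect_true(all(v >= 0 & v <= 1, na.rm = TRUE))
  expect_gt(mean(v[sc$truth_mask$labels == 1L]),
            mean(v[sc$truth_mask$labels == 3L]))
})

test_that("a spectrally uniform scene has no shadow contrast to scale", {
  wl <- default_grid
  leaf <- endmember_spectrum("leaf", wl, n_pct = 2.6)$reflectance
  arr <- array(rep(leaf, each = 16), dim = c(4, 4, length(wl)))
  expect_error(ndcsi_image(spectral_cube(arr, wl)), "degenerate")
})

test_that("histogram intersection finds the class boundary", {
  # disjoint supports: midpoint of the gap
  a <- seq(0.10, 0.30, length.out = 50)
  b <- seq(0.50, 0.70, length.out = 50)
  expect_equal(histogram_intersection_threshold(a, b), 0.4)

  # two well-separated Gaussians: crossing near the midpoint, and within one
  # bin width of the exhaustive misclassification-minimizing scan
  set.seed(31)
  a <- rnorm(10000, 0.2, 0.05); b <- rnorm(10000, 0.8, 0.05)
  th <- histogram_intersection_threshold(a, b, n_bins = 100)
  expect_lt(abs(th - 0.5), 0.05)
  bin_w <- diff(range(c(a, b))) / 100
  expect_lt(abs(th - brute_threshold_scan(a, b, 100)), bin_w + 1e-12)

  # indistinguishable classes are an error
  expect_error(histogram_intersection_threshold(a, a), "identical")
})

test_that("sequential thresholding recovers the synthetic ground truth", {
  sc <- generate_scene(scene_config(seed = 13))
  mask <- classify_pixels(sc$cube)
  rep_ <- segmentation_accuracy(mask, sc$truth_mask)
  expect_gte(rep_$overall_accuracy, 0.99)
  expect_gte(rep_$kappa, 0.98)

  # extreme NDVI threshold: nothing survives the soil mask
  quiet <- generate_scene(scene_config(n_trees = 4, noise_sd = 0, seed = 13))
  all_soil <- classify_pixels(quiet$cube, threshold_pair(ndvi = 0.9999))
  expect_true(all(all_soil$labels == 2L))

  # deterministic: same cube and thresholds, same labels
  expect_identical(classify_pixels(sc$cube)$labels, mask$labels)
})

test_that("segmentation accuracy reproduces hand-computed confusions", {
  t_half <- class_mask(matrix(rep(1:2, each = 50), 10, 10))
  p_all <- class_mask(matrix(1L, 10, 10))
  r <- segmentation_accuracy(p_all, t_half)
  expect_equal(r$overall_accuracy, 0.5)
  expect_equal(r$kappa, 0)

  # identity prediction
  ri <- segmentation_accuracy(t_half, t_half)
  expect_equal(ri$overall_accuracy, 1)
  expect_equal(ri$kappa, 1)
  expect_equal(ri$overlap_fraction_a_in_b, 1)
  expect_equal(ri$overlap_fraction_b_in_a, 1)

  # 3-class toy confusion [[40,5,5],[4,40,6],[1,4,45]]:
  # OA = 125/150, kappa = (OA - 1/3)/(2/3) = 0.75
  truth <- rep(1:3, each = 50)
  pred <- c(rep(1, 40), rep(2, 5), rep(3, 5),
            rep(1, 4), rep(2, 40), rep(3, 6),
            rep(1, 1), rep(2, 4), rep(3, 45))
  rt <- segmentation_accuracy(class_mask(matrix(pred, 10, 15)),
                              class_mask(matrix(truth, 10, 15)))
  expect_equal(rt$overall_accuracy, 125 / 150)
  expect_equal(rt$kappa, 0.75)
})

test_that("scoring restricted to sample points uses only those points", {
  truth <- class_mask(matrix(rep(1:2, each = 8), 4, 4))
  pred <- class_mask(matrix(1L, 4, 4))
  pts <- data.frame(row = c(0, 1, 2, 3), col = c(0, 0, 0, 0))  # truth canopy
  r <- segmentation_accuracy(pred, truth, sample_points = pts)
  expect_equal(r$overall_accuracy, 1)
  expect_error(segmentation_accuracy(pred, truth,
                                     sample_points = data.frame(row = 9, col = 0)),
               "outside")
})
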