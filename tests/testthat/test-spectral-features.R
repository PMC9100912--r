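test_that("first derivative is exact on polynomials", {
  wl <- seq(500, 700, 10)
  lin <- spectrum(0.1 + 0.001 * (wl - 500), wl)
  d <- first_derivative(lin)
  expect_equal(d$derivative, rep(0.001, length(wl)))

  quad <- spectrum(1e-6 * (wl - 500)^2, wl)
  dq <- first_derivative(quad)
  interior <- 2:(length(wl) - 1)
  expect_equal(dq$derivative[interior], 2e-6 * (wl[interior] - 500))

  const <- spectrum(rep(0.3, length(wl)), wl)
  expect_true(all(first_derivative(const)$derivative == 0))
  expect_error(first_derivative(spectrum(c(0.1, 0.2), c(500, 510))), "3 bands")
})

test_that("ROI mean spectra average canopy pixels only", {
  wl <- c(500, 600, 700)
  arr <- array(0.2, dim = c(5, 5, 3))
  arr[3, 4, ] <- 0.4  # second canopy pixel
  cube <- spectral_cube(arr, wl)
  labels <- matrix(2L, 5, 5)
  labels[3, 3] <- 1L; labels[3, 4] <- 1L
  mask <- class_mask(labels)

  s <- roi_mean_spectrum(cube, mask, row = 2, col = 2, radius = 1.5)
  expect_equal(s$reflectance, rep(0.3, 3))  # mean of 0.2 and 0.4
  expect_equal(attr(s, "pixel_count"), 2L)

  # all canopy pixels identical -> that spectrum back
  s1 <- roi_mean_spectrum(cube, mask, row = 2, col = 2, radius = 0.5)
  expect_equal(s1$reflectance, rep(0.2, 3))

  # ROI over soil only: explicit error naming the tree
  expect_error(roi_mean_spectrum(cube, mask, row = 0, col = 0, radius = 1,
                                 tree_id = "T42"), "T42")
})

toy_vi_spectrum <- function() {
  toy_spectrum(c(`445` = 0.05, `550` = 0.12, `670` = 0.06, `702` = 0.10,
                 `705` = 0.11, `720` = 0.18, `722` = 0.19, `730` = 0.25,
                 `750` = 0.40, `840` = 0.48, `870` = 0.47))
}

test_that("vegetation indices follow the published formulas exactly", {
  vi <- vegetation_indices(toy_vi_spectrum())
  expect_equal(vi$mSR705, (0.40 - 0.05) / (0.11 - 0.05))
  expect_equal(vi$mSR705, 5.83333, tolerance = 1e-5)
  expect_equal(vi$mND705, (0.40 - 0.11) / (0.40 + 0.11 - 2 * 0.05))
  expect_equal(vi$CI_rededge, (0.48 - 0.47) / (0.18 - 0.25) - 1)
  expect_equal(vi$CI_green, (0.48 - 0.47) / 0.12 - 1)
  expect_equal(vi$CI_green, -0.91667, tolerance = 1e-5)
  expect_equal(vi$DCNI, ((0.19 - 0.10) / (0.10 - 0.06)) / (0.19 - 0.06 + 0.03))
})

test_that("flat spectra yield the sentinels the printed formulas force", {
  flat <- spectrum(rep(0.2, 11), toy_vi_spectrum()$wavelengths)
  vi <- vegetation_indices(flat)
  expect_true(is.na(vi$mSR705))
  expect_true(is.na(vi$mND705))
  expect_true(is.na(vi$CI_rededge))
  expect_equal(vi$CI_green, -1)
  expect_true(is.na(vi$DCNI))
})

test_that("indices ignore bands they do not reference", {
  s <- toy_vi_spectrum()
  vi <- vegetation_indices(s)
  padded <- spectrum(c(s$reflectance, 0.5, 0.55),
                     c(s$wavelengths, 900, 950))
  expect_equal(unclass(vegetation_indices(padded)), unclass(vi),
               ignore_attr = TRUE)
})

test_that("the literature CI variant uses band sums, not differences", {
  vi <- vegetation_indices(toy_vi_spectrum(), variant = "literature")
  expect_equal(vi$CI_green, ((0.48 + 0.47) / 2) / 0.12 - 1)
  expect_equal(vi$CI_rededge, ((0.48 + 0.47) / 2) / ((0.18 + 0.25) / 2) - 1)
})

test_that("red-edge parameters locate the derivative maximum", {
  wl <- default_grid
  # logistic spectrum with inflection at 722 nm
  s <- spectrum(0.1 + 0.4 * plogis((wl - 722) / 10), wl)
  re <- red_edge_parameters(first_derivative(s))
  expect_lte(abs(re$REP - 722), 4)
  expect_true(re$REP >= 680 && re$REP <= 750)
  expect_gte(re$Dr, re$Drmin)
  expect_gte(re$DDr, 0)
  expect_true(abs(re$NDDr) <= 1)
  # integral of the derivative recovers the reflectance rise over the window
  i680 <- which.min(abs(wl - 682)); i750 <- which.min(abs(wl - 750))
  rise <- s$reflectance[i750] - s$reflectance[i680]
  expect_equal(re$SDr, rise, tolerance = 0.02)
})

test_that("a linear spectrum degenerates every red-edge parameter", {
  wl <- seq(600, 800, 5)  # grid containing 680 and 750 exactly
  cc <- 0.002
  s <- spectrum(0.05 + cc * (wl - 600), wl)
  re <- red_edge_parameters(first_derivative(s))
  expect_equal(re$Dr, cc)
  expect_equal(re$Drmin, cc)
  expect_equal(re$NDDr, 0)
  expect_equal(re$RDr, 1)
  expect_equal(re$DDr, 0)
  expect_equal(re$SDr, cc * 70)  # 680-750 nm window
})

test_that("vectorized features agree with the per-spectrum path", {
  wl <- default_grid
  ns <- c(2.2, 2.6, 3.0)
  R <- t(vapply(ns, function(n) endmember_spectrum("leaf", wl, n_pct = n)$reflectance,
                numeric(length(wl))))
  spec <- feature_spec(
    two_band = data.frame(index_type = c("NDSI", "RSI"),
                          lambda_i = c(662, 466), lambda_j = c(782, 542)),
    red_edge = c("REP", "Dr", "Drmin", "NDDr", "RDr", "DDr", "SDr"))
  FT <- compute_feature_matrix(R, wl, spec)
  expect_equal(nrow(FT), 3)
  expect_equal(ncol(FT), 9)
  for (k in seq_along(ns)) {
    s <- spectrum(R[k, ], wl)
    re <- red_edge_parameters(first_derivative(s))
    for (nm in c("REP", "Dr", "Drmin", "NDDr", "RDr", "DDr", "SDr")) {
      expect_equal(unname(FT[k, nm]), re[[nm]], tolerance = 1e-12)
    }
    i <- which(wl == 662); j <- which(wl == 782)
    expect_equal(unname(FT[k, "NDSI_662_782"]),
                 (R[k, i] - R[k, j]) / (R[k, i] + R[k, j]))
  }
})
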