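test_that("leaf red edge shifts monotonically with nitrogen", {
  wl <- default_grid
  rep_of <- function(n) {
    red_edge_parameters(first_derivative(endmember_spectrum("leaf", wl, n_pct = n)))$REP
  }
  # inflection moves 12 nm per % N; grid quantizes REP to 4 nm steps
  expect_lt(abs((rep_of(3.0) - rep_of(2.1)) - 10.8), 4.1)
  reps <- vapply(seq(2.1, 3.1, by = 0.1), rep_of, numeric(1))
  expect_true(all(diff(reps) >= 0))
  expect_true(all(reps[-(1:5)] > reps[1]))  # strict over a 0.5% N gap

  # red-band reflectance strictly decreases with nitrogen
  r662 <- vapply(seq(1.5, 3.5, by = 0.1), function(n) {
    s <- endmember_spectrum("leaf", wl, n_pct = n)
    s$reflectance[which.min(abs(wl - 662))]
  }, numeric(1))
  expect_true(all(diff(r662) < 0))
})

test_that("shadow endmember is an exact attenuated copy of its base", {
  wl <- default_grid
  leaf <- endmember_spectrum("leaf", wl, n_pct = 2.6)
  sh <- endmember_spectrum("shadow", wl, base = leaf, attenuation = 0.2)
  expect_equal(sh$reflectance, 0.2 * leaf$reflectance)
})

test_that("soil is less vegetated than any leaf in the red/NIR plane", {
  wl <- default_grid
  ndvi_of <- function(s) {
    r <- s$reflectance[which.min(abs(wl - 662))]
    n <- s$reflectance[which.min(abs(wl - 782))]
    (n - r) / (n + r)
  }
  soil <- ndvi_of(endmember_spectrum("soil", wl))
  for (n in c(2.1, 2.6, 3.1, 3.5)) {
    expect_lt(soil, ndvi_of(endmember_spectrum("leaf", wl, n_pct = n)))
  }
})

test_that("endmember spectra stay inside (0, 1) and validate inputs", {
  wl <- default_grid
  for (n in c(1.5, 2.622, 3.5)) {
    s <- endmember_spectrum("leaf", wl, n_pct = n)
    expect_true(all(s$reflectance > 0 & s$reflectance < 1))
  }
  expect_error(endmember_spectrum("leaf", wl, n_pct = 4.0), "n_pct")
  expect_error(endmember_spectrum("leaf", numeric(0), n_pct = 2.5))
})

test_that("nitrogen field reproduces the target distribution", {
  expect_equal(nitrogen_field(10, n_sd = 0), rep(2.622, 10))
  x1 <- nitrogen_field(500, seed = 42)
  x2 <- nitrogen_field(500, seed = 42)
  expect_identical(x1, x2)
  expect_lt(abs(mean(x1) - 2.622), 0.03)
  expect_lt(abs(sd(x1) - 0.193), 0.03)
  expect_true(all(x1 >= 1.5 & x1 <= 3.5))
  expect_error(nitrogen_field(1), "n_trees")
  expect_error(nitrogen_field(10, n_sd = -1), "n_sd")
})

test_that("generated scenes carry all three classes and exact ground truth", {
  cfg <- scene_config(n_trees = 9, seed = 3)
  sc <- generate_scene(cfg)
  expect_setequal(unique(as.vector(sc$truth_mask$labels)), 1:3)
  expect_equal(nrow(sc$samples), 9)
  expect_true(all(sc$samples$n_pct >= 1.5 & sc$samples$n_pct <= 3.5))
  # every tree has canopy pixels at its recorded centre
  for (k in seq_len(9)) {
    expect_equal(sc$truth_mask$labels[round(sc$samples$row[k]) + 1,
                                      round(sc$samples$col[k]) + 1], 1L)
  }
  # class fractions match the geometry: 9 crowns of radius 10
  canopy_frac <- mean(sc$truth_mask$labels == 1L)
  expect_lt(abs(canopy_frac - 9 * pi * 10^2 / (120 * 120)), 0.01)
})

test_that("a noise-free scene renders each crown's spectrum exactly", {
  cfg <- scene_config(n_trees = 4, noise_sd = 0, seed = 5)
  sc <- generate_scene(cfg)
  k <- 2L
  leaf <- endmember_spectrum("leaf", scene_wavelengths(cfg),
                             n_pct = sc$samples$n_pct[k])
  px <- sc$cube$reflectance[round(sc$samples$row[k]) + 1,
                            round(sc$samples$col[k]) + 1, ]
  expect_equal(px, leaf$reflectance)
})

test_that("scene generation is deterministic in the seed", {
  cfg <- scene_config(seed = 99)
  a <- generate_scene(cfg)
  b <- generate_scene(cfg)
  expect_identical(a$cube$reflectance, b$cube$reflectance)
  expect_identical(a$samples$n_pct, b$samples$n_pct)
})

test_that("overcrowded scenes are rejected", {
  expect_error(generate_scene(scene_config(n_rows = 30, n_cols = 30, n_trees = 9)),
               "too small")
})
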