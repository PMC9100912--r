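# Synthetic orchard scenes: circular crowns on a soil background with offset
# cast/self shadows, per-tree nitrogen driving a logistic red-edge leaf model.
# The generator exists so that every downstream stage (segmentation, feature
# extraction, band screening, model fits, mapping) can be exercised against
# known ground truth.

#' Scene generator configuration
#'
#' Defaults emulate the study conditions this package targets: a 450-950 nm
#' grid sampled at 4 nm (126 bands), and tree nitrogen drawn from a truncated
#' normal with mean 2.622% and SD 0.193% on [1.5, 3.5]%.
#'
#' @param n_rows,n_cols scene size in pixels.
#' @param wavelength_start,wavelength_end,wavelength_step band grid, nm.
#' @param n_trees number of crowns, laid out on a regular planting grid.
#' @param crown_radius crown radius, pixels.
#' @param shadow_offset integer (row, col) pixel offset of each crown's
#'   shadow disc.
#' @param shadow_attenuation multiplicative attenuation applied to the
#'   occluded surface's spectrum, in (0, 1).
#' @param n_mean,n_sd tree nitrogen distribution, % of dry mass.
#' @param noise_sd per-pixel Gaussian reflectance noise SD.
#' @param seed integer seed; fully determines the scene.
#' @return a `scene_config` list.
#' @export
scene_config <- function(n_rows = 120, n_cols = 120,
                         wavelength_start = 450, wavelength_end = 950,
                         wavelength_step = 4,
                         n_trees = 9, crown_radius = 10,
                         shadow_offset = c(7, 7), shadow_attenuation = 0.25,
                         n_mean = 2.622, n_sd = 0.193,
                         noise_sd = 0.005, seed = 1L) {
  span <- wavelength_end - wavelength_start
  if (wavelength_step <= 0 || span <= 0 ||
      abs(span / wavelength_step - round(span / wavelength_step)) > 1e-9) {
    stop("wavelength range must be increasing and divisible by the step", call. = FALSE)
  }
  if (n_sd < 0) stop("n_sd must be >= 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (shadow_attenuation <= 0 || shadow_attenuation >= 1) {
    stop("shadow_attenuation must lie in (0, 1)", call. = FALSE)
  }
  if (n_trees < 1) stop("n_trees must be >= 1", call. = FALSE)
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 wavelength_start = wavelength_start,
                 wavelength_end = wavelength_end,
                 wavelength_step = wavelength_step,
                 n_trees = as.integer(n_trees),
                 crown_radius = crown_radius,
                 shadow_offset = as.integer(shadow_offset),
                 shadow_attenuation = shadow_attenuation,
                 n_mean = n_mean, n_sd = n_sd,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "scene_config")
}

#' Wavelength grid implied by a scene configuration
#' @param config a [scene_config()].
#' @return numeric vector of band centres, nm.
#' @export
scene_wavelengths <- function(config) {
  seq(config$wavelength_start, config$wavelength_end, by = config$wavelength_step)
}

# Nitrogen -> leaf-model coupling constants. The red-edge inflection moves
# 12 nm per % N around 700 nm at N = 2.0%, red reflectance falls with N
# (more chlorophyll absorbs more red light), the NIR plateau stays at 0.50.
# These are documented stand-ins carrying a monotone N -> red-edge signal;
# they are not calibrated to any cultivar.
.leaf_lambda_infl <- function(n_pct) 700 + 12 * (n_pct - 2.0)
.leaf_r_red <- function(n_pct) 0.09 - 0.02 * (n_pct - 2.0)
.leaf_r_nir <- 0.50
.leaf_slope_nm <- 10

#' Endmember reflectance spectra for the synthetic scene
#'
#' Three parametric endmembers: `leaf` is a logistic red edge
#' `R_red + (R_nir - R_red) / (1 + exp(-(lambda - lambda_infl)/s))` with a
#' green reflectance bump and a chlorophyll absorption dip near 670 nm, with
#' `lambda_infl = 700 + 12 (N - 2)` nm and red reflectance decreasing in N;
#' `soil` is an affine spectrum rising from 0.15 to 0.30 across the grid;
#' `shadow` is the occluded surface's spectrum scaled by an attenuation
#' factor, which preserves spectral shape while shrinking the derivative
#' amplitude.
#'
#' @param kind one of `"leaf"`, `"soil"`, `"shadow"`.
#' @param wavelengths band grid, nm.
#' @param n_pct leaf nitrogen, % in `[1.5, 3.5]` (leaf only).
#' @param base a [spectrum()] to attenuate (shadow only).
#' @param attenuation multiplicative factor in (0, 1) (shadow only).
#' @return a [spectrum()].
#' @export
endmember_spectrum <- function(kind = c("leaf", "soil", "shadow"), wavelengths,
                               n_pct = NULL, base = NULL, attenuation = NULL) {
  kind <- match.arg(kind)
  check_wavelengths(wavelengths)
  wl <- as.numeric(wavelengths)
  refl <- switch(kind,
    leaf = {
      if (is.null(n_pct) || n_pct < 1.5 || n_pct > 3.5) {
        stop("leaf endmember requires n_pct in [1.5, 3.5]", call. = FALSE)
      }
      r_red <- .leaf_r_red(n_pct)
      logistic <- stats::plogis((wl - .leaf_lambda_infl(n_pct)) / .leaf_slope_nm)
      green_bump <- 0.04 * exp(-(wl - 550)^2 / (2 * 30^2))
      chl_dip <- (0.015 + 0.005 * (n_pct - 2.0)) * exp(-(wl - 670)^2 / (2 * 12^2))
      r_red + (.leaf_r_nir - r_red) * logistic + green_bump - chl_dip
    },
    soil = {
      # affine brightening with wavelength, 0.15 at 450 nm to 0.30 at 950 nm
      0.15 + 0.15 * (wl - 450) / 500
    },
    shadow = {
      if (is.null(base) || !inherits(base, "spectrum")) {
        stop("shadow endmember requires a base spectrum", call. = FALSE)
      }
      if (is.null(attenuation) || attenuation <= 0 || attenuation >= 1) {
        stop("shadow attenuation must lie in (0, 1)", call. = FALSE)
      }
      if (!isTRUE(all.equal(base$wavelengths, wl))) {
        stop("base spectrum must share the requested wavelength grid", call. = FALSE)
      }
      base$reflectance * attenuation
    }
  )
  if (any(refl <= 0) || any(refl >= 1)) {
    stop("endmember reflectance left (0, 1); check coupling constants", call. = FALSE)
  }
  spectrum(refl, wl)
}

#' Draw per-tree nitrogen concentrations
#'
#' Truncated-normal draws on `[lower, upper]` via the inverse-CDF transform,
#' so a fixed seed reproduces the field exactly. `n_sd = 0` degenerates to
#' all trees at the mean.
#'
#' @param n_trees number of trees (>= 2).
#' @param n_mean,n_sd normal parameters before truncation, % N.
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @param lower,upper truncation bounds, % N.
#' @return numeric vector of length `n_trees`.
#' @export
nitrogen_field <- function(n_trees, n_mean = 2.622, n_sd = 0.193, seed = NULL,
                           lower = 1.5, upper = 3.5) {
  if (n_trees < 2) stop("n_trees must be >= 2", call. = FALSE)
  if (n_sd < 0) stop("n_sd must be >= 0", call. = FALSE)
  if (n_sd == 0) return(rep(n_mean, n_trees))
  draw <- function() {
    p_lo <- stats::pnorm(lower, n_mean, n_sd)
    p_hi <- stats::pnorm(upper, n_mean, n_sd)
    stats::qnorm(stats::runif(n_trees, p_lo, p_hi), n_mean, n_sd)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Generate a synthetic orchard scene
#'
#' Lays `n_trees` circular crowns on a regular planting grid over a soil
#' background, gives each crown a nitrogen-driven leaf spectrum, renders a
#' shadow disc offset from each crown (attenuated copy of that crown's leaf
#' spectrum, i.e. crown self/cast shadow), adds per-pixel Gaussian noise,
#' and records the ground-truth class mask and per-tree sample table.
#'
#' @param config a [scene_config()].
#' @return a list of class `scene_bundle` with elements `cube`
#'   ([spectral_cube()]), `truth_mask` ([class_mask()]), `samples`
#'   ([sample_table()]) and `generator_params`.
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  wl <- scene_wavelengths(config)
  nb <- length(wl)
  nr <- config$n_rows; nc <- config$n_cols

  # planting grid
  cols_t <- ceiling(sqrt(config$n_trees))
  rows_t <- ceiling(config$n_trees / cols_t)
  cell_h <- nr / rows_t; cell_w <- nc / cols_t
  reach <- config$crown_radius + max(abs(config$shadow_offset)) + 1
  if (cell_h < 2 * reach || cell_w < 2 * reach) {
    stop(sprintf("scene too small: %d trees need cells of at least %.0f px, have %.0f x %.0f",
                 config$n_trees, 2 * reach, cell_h, cell_w), call. = FALSE)
  }
  k <- seq_len(config$n_trees) - 1L
  centre_row <- (k %/% cols_t + 0.5) * cell_h   # 0-based pixel coordinates
  centre_col <- (k %% cols_t + 0.5) * cell_w

  with_seed(config$seed, {
    n_pct <- nitrogen_field(config$n_trees, config$n_mean, config$n_sd,
                            seed = NULL)

    labels <- matrix(2L, nr, nc)  # soil background
    # pixel centre coordinate grids (0-based)
    rr <- matrix(seq_len(nr) - 1L, nr, nc)
    cc <- matrix(rep(seq_len(nc) - 1L, each = nr), nr, nc)

    crown_of <- matrix(0L, nr, nc)   # which tree owns each canopy pixel
    shade_of <- matrix(0L, nr, nc)
    r2 <- config$crown_radius^2
    for (t in seq_len(config$n_trees)) {
      d2 <- (rr - centre_row[t])^2 + (cc - centre_col[t])^2
      crown <- d2 <= r2
      crown_of[crown] <- t
      d2s <- (rr - centre_row[t] - config$shadow_offset[1])^2 +
             (cc - centre_col[t] - config$shadow_offset[2])^2
      shade_of[d2s <= r2 & shade_of == 0L] <- t
    }
    shade_of[crown_of > 0L] <- 0L  # crowns take precedence over shadows
    labels[crown_of > 0L] <- 1L
    labels[shade_of > 0L] <- 3L

    soil <- endmember_spectrum("soil", wl)
    leaf_spectra <- lapply(n_pct, function(n) endmember_spectrum("leaf", wl, n_pct = n))

    cube <- array(rep(soil$reflectance, each = nr * nc), dim = c(nr, nc, nb))
    for (t in seq_len(config$n_trees)) {
      crown_idx <- which(crown_of == t)
      shade_idx <- which(shade_of == t)
      lf <- leaf_spectra[[t]]$reflectance
      for (b in seq_len(nb)) {
        plane <- (b - 1L) * nr * nc
        cube[plane + crown_idx] <- lf[b]
        cube[plane + shade_idx] <- lf[b] * config$shadow_attenuation
      }
    }
    if (config$noise_sd > 0) {
      cube <- cube + stats::rnorm(length(cube), sd = config$noise_sd)
      cube <- pmin(pmax(cube, 1e-6), 1 - 1e-6)
    }

    samples <- sample_table(
      tree_id = sprintf("T%03d", seq_len(config$n_trees)),
      row = centre_row, col = centre_col,
      radius_px = config$crown_radius, n_pct = n_pct)

    bundle <- list(cube = spectral_cube(cube, wl),
                   truth_mask = class_mask(labels),
                   samples = samples,
                   generator_params = list(config = config, n_pct = n_pct,
                                           centre_row = centre_row,
                                           centre_col = centre_col))
    class(bundle) <- "scene_bundle"
    bundle
  })
}
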