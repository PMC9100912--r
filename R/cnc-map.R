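# Spatial nitrogen inversion: apply a fitted model to every canopy pixel's
# spectrum to render the CNC distribution raster, plus per-tree summaries.

#' Predict a per-pixel nitrogen map
#'
#' Computes the model's feature vector from each canopy pixel's spectrum
#' (two-band indices and red-edge parameters per pixel) and applies the
#' model. Non-canopy pixels are `NA`. Predictions are clipped to the
#' plausible nitrogen range (default 1-4% N) and the number of clipped
#' pixels is recorded in the provenance, together with the feature spec,
#' segmentation thresholds (when carried by the mask) and any model seed, so
#' a rerun reproduces the raster exactly.
#'
#' @param cube a [spectral_cube()].
#' @param mask a [class_mask()] paired with `cube`.
#' @param model a fitted `cnc_curve_fit`, `cnc_plsr` or `cnc_bpnn`.
#' @param spec the [feature_spec()] describing the model's input columns.
#' @param clip prediction clipping range, % N.
#' @return a `cnc_map`: list with `values` (matrix, % N, `NA` off-canopy)
#'   and `provenance`.
#' @export
predict_map <- function(cube, mask, model, spec, clip = c(1, 4)) {
  stopifnot(inherits(cube, "spectral_cube"), inherits(mask, "class_mask"),
            inherits(spec, "feature_spec"))
  d <- dim(cube$reflectance)
  if (!all(dim(mask$labels) == d[1:2])) stop("mask and cube shapes differ", call. = FALSE)
  canopy_idx <- which(mask$labels == 1L & !cube$nodata_mask)
  if (!length(canopy_idx)) stop("no canopy pixels to predict", call. = FALSE)
  npix <- length(canopy_idx); nb <- d[3]
  R <- matrix(0, npix, nb)
  for (b in seq_len(nb)) {
    R[, b] <- cube$reflectance[(b - 1L) * d[1] * d[2] + canopy_idx]
  }
  FT <- compute_feature_matrix(R, cube$wavelengths, spec)
  preds <- predict(model, FT)
  if (length(preds) != npix) stop("model/feature mismatch", call. = FALSE)
  n_clipped <- sum(preds < clip[1] | preds > clip[2], na.rm = TRUE)
  preds <- pmin(pmax(preds, clip[1]), clip[2])
  values <- matrix(NA_real_, d[1], d[2])
  values[canopy_idx] <- preds
  structure(list(
    values = values,
    provenance = list(model_class = class(model)[1],
                      model_seed = model$seed,
                      feature_spec = spec,
                      thresholds = attr(mask, "thresholds"),
                      clip = clip, n_clipped = n_clipped,
                      n_canopy_pixels = npix)
  ), class = "cnc_map")
}

#' Per-tree summary of a nitrogen map
#'
#' Mean, SD and pixel count of map values within each tree's ROI disc.
#' An ROI with no mapped canopy pixels is reported with `pixel_count` 0 and
#' an undefined mean, not treated as an error.
#'
#' @param map a [predict_map()] result.
#' @param samples a [sample_table()].
#' @return `data.frame(tree_id, mean, sd, pixel_count)`.
#' @export
per_tree_summary <- function(map, samples) {
  stopifnot(inherits(map, "cnc_map"), inherits(samples, "sample_table"))
  d <- dim(map$values)
  rr <- matrix(seq_len(d[1]) - 1L, d[1], d[2])
  cc <- matrix(rep(seq_len(d[2]) - 1L, each = d[1]), d[1], d[2])
  out <- lapply(seq_len(nrow(samples)), function(k) {
    sel <- (rr - samples$row[k])^2 + (cc - samples$col[k])^2 <= samples$radius_px[k]^2
    v <- map$values[sel]
    v <- v[!is.na(v)]
    data.frame(tree_id = samples$tree_id[k],
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) stats::sd(v) else if (length(v) == 1) 0 else NA_real_,
               pixel_count = length(v))
  })
  do.call(rbind, out)
}

#' Write or read a nitrogen map as a float TIFF
#'
#' Stored value is `N% / 10` so the 1-4% N clip range sits inside the TIFF
#' float range; off-canopy pixels are stored as 0 (an impossible value,
#' since mapped nitrogen is at least the 1% clip floor) and restored to `NA`
#' on read.
#'
#' @param map a `cnc_map`.
#' @param path `.tif` path.
#' @return `path` (write) / matrix of % N with `NA` off canopy (read).
#' @export
write_cnc_map <- function(map, path) {
  stopifnot(inherits(map, "cnc_map"))
  v <- map$values / 10
  v[is.na(v)] <- 0
  tiff::writeTIFF(v, path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_cnc_map
#' @export
read_cnc_map <- function(path) {
  v <- tiff::readTIFF(path)
  if (length(dim(v)) == 3) v <- v[, , 1]
  v <- v * 10
  v[v == 0] <- NA_real_
  v
}
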