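# End-to-end workflow drivers: per-tree feature tables and the full
# simulate -> segment -> extract -> screen -> fit -> evaluate -> map chain.

#' Per-tree canopy feature table
#'
#' Extracts each tree's ROI mean canopy spectrum (using the supplied mask)
#' and computes the features named by `spec`, returning one row per tree
#' with its measured nitrogen.
#'
#' @param cube a [spectral_cube()].
#' @param mask a [class_mask()].
#' @param samples a [sample_table()].
#' @param spec a [feature_spec()].
#' @return `data.frame` with `tree_id`, `n_pct`, then one column per feature.
#' @export
build_feature_table <- function(cube, mask, samples, spec) {
  stopifnot(inherits(samples, "sample_table"))
  S <- roi_spectra_matrix(cube, mask, samples)
  FT <- compute_feature_matrix(S, cube$wavelengths, spec)
  cbind(data.frame(tree_id = samples$tree_id, n_pct = samples$n_pct),
        as.data.frame(FT))
}

#' ROI mean spectra for all trees as a matrix
#'
#' @param cube a [spectral_cube()].
#' @param mask a [class_mask()].
#' @param samples a [sample_table()].
#' @return matrix `[trees x bands]`, rownames = tree IDs.
#' @export
roi_spectra_matrix <- function(cube, mask, samples) {
  S <- t(vapply(seq_len(nrow(samples)), function(k) {
    roi_mean_spectrum(cube, mask, samples$row[k], samples$col[k],
                      samples$radius_px[k], tree_id = samples$tree_id[k])$reflectance
  }, numeric(length(cube$wavelengths))))
  rownames(S) <- samples$tree_id
  S
}

#' Run the whole nitrogen-retrieval workflow on a synthetic scene
#'
#' Chains scene generation, NDVI/NDCSI segmentation, segmentation scoring
#' against the ground truth, ROI spectrum extraction, exhaustive two-band
#' screening (NDSI, RSI, DSI), feature assembly (top pair per index type
#' plus NDDr, RDr, SDr), the rank-ordered 3:1 split, PLSR and network fits
#' on the modeling set, validation metrics, and (optionally) the per-pixel
#' nitrogen map with per-tree summaries.
#'
#' @param config a [scene_config()]; its seed drives every stochastic step.
#' @param thresholds segmentation [threshold_pair()].
#' @param r_floor correlation floor for pair screening.
#' @param n_components PLSR components.
#' @param render_map also render the per-pixel map from the network model?
#' @return a list with the intermediate products and fitted models; see
#'   element names.
#' @export
run_cnc_pipeline <- function(config, thresholds = threshold_pair(),
                             r_floor = 0.45, n_components = 3,
                             render_map = FALSE) {
  scene <- generate_scene(config)
  mask <- classify_pixels(scene$cube, thresholds)
  seg <- segmentation_accuracy(mask, scene$truth_mask)

  S <- roi_spectra_matrix(scene$cube, mask, scene$samples)
  y <- scene$samples$n_pct
  maps <- lapply(c(NDSI = "NDSI", RSI = "RSI", DSI = "DSI"), function(ty) {
    pairwise_correlation_map(S, scene$cube$wavelengths, y, index_type = ty)
  })
  pairs <- select_sensitive_pairs(maps, r_floor = r_floor, top_k = 1)

  spec <- feature_spec(two_band = pairs[, c("index_type", "lambda_i", "lambda_j")],
                       red_edge = c("NDDr", "RDr", "SDr"))
  features <- build_feature_table(scene$cube, mask, scene$samples, spec)

  split <- split_samples(scene$samples)
  fcols <- setdiff(names(features), c("tree_id", "n_pct"))
  Xm <- as.matrix(features[match(split$modeling_ids, features$tree_id), fcols])
  ym <- features$n_pct[match(split$modeling_ids, features$tree_id)]
  Xv <- as.matrix(features[match(split$validation_ids, features$tree_id), fcols])
  yv <- features$n_pct[match(split$validation_ids, features$tree_id)]

  plsr <- fit_plsr(Xm, ym, n_components = min(n_components, ncol(Xm)))
  bpnn <- fit_bpnn(Xm, ym, seed = config$seed)

  res <- list(
    scene = scene, mask = mask, segmentation = seg,
    correlation_maps = maps, selected_pairs = pairs,
    feature_spec = spec, features = features, split = split,
    plsr = plsr, bpnn = bpnn,
    plsr_modeling = eval_metrics(ym, predict(plsr, Xm)),
    plsr_validation = eval_metrics(yv, predict(plsr, Xv)),
    bpnn_modeling = eval_metrics(ym, predict(bpnn, Xm)),
    bpnn_validation = eval_metrics(yv, predict(bpnn, Xv))
  )
  if (render_map) {
    res$cnc_map <- predict_map(scene$cube, mask, bpnn, spec)
    res$tree_summary <- per_tree_summary(res$cnc_map, scene$samples)
  }
  res
}
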