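# Canopy segmentation: NDVI and NDCSI index images, histogram-intersection
# threshold selection, sequential soil-then-shadow masking, and segmentation
# accuracy scoring (overall accuracy, kappa, canopy overlap fractions).

#' Normalized-difference index image from two bands
#'
#' Per-pixel `(R_a - R_b)/(R_a + R_b)` after snapping the requested
#' wavelengths to the nearest bands (strict: within half a grid step).
#' Pixels where the denominator vanishes get `NA`.
#'
#' @param cube a [spectral_cube()].
#' @param lambda_a,lambda_b requested wavelengths, nm.
#' @param name index name recorded on the result.
#' @return an `index_image`: list with `values` (matrix), `name`,
#'   `source_wavelengths` (the resolved band centres).
#' @export
normalized_difference_image <- function(cube, lambda_a, lambda_b, name = "NDSI") {
  stopifnot(inherits(cube, "spectral_cube"))
  ia <- resolve_wavelength(lambda_a, cube$wavelengths)
  ib <- resolve_wavelength(lambda_b, cube$wavelengths)
  Ra <- cube$reflectance[, , ia]
  Rb <- cube$reflectance[, , ib]
  vals <- safe_div(Ra - Rb, Ra + Rb)
  vals[cube$nodata_mask] <- NA_real_
  structure(list(values = vals, name = name,
                 source_wavelengths = cube$wavelengths[c(ia, ib)]),
            class = "index_image")
}

#' NDVI image
#'
#' The red/NIR normalized difference `(R_nir - R_red)/(R_nir + R_red)`.
#' Default bands 662 nm (red) and 782 nm (NIR) reuse the red/NIR pair the
#' exhaustive two-band screening finds most nitrogen-sensitive; both are
#' configurable.
#'
#' @param cube a [spectral_cube()].
#' @param red,nir band wavelengths, nm.
#' @return an `index_image`.
#' @export
ndvi_image <- function(cube, red = 662, nir = 782) {
  normalized_difference_image(cube, nir, red, name = "NDVI")
}

# Registry of NDCSI formulas. The shadow index is pluggable because its
# published definition is not reproducible from the sources at hand; the
# default is an explicit stand-in documented below.
.ndcsi_registry <- new.env(parent = emptyenv())

#' Register or look up an NDCSI formula
#'
#' A formula is `function(cube) -> matrix` of per-pixel index values.
#'
#' @param name registry key.
#' @param fn formula function, or `NULL` to look up.
#' @return the formula function, invisibly on registration.
#' @export
ndcsi_formula <- function(name, fn = NULL) {
  if (is.null(fn)) {
    if (!exists(name, envir = .ndcsi_registry, inherits = FALSE)) {
      stop("unknown NDCSI formula: ", name, call. = FALSE)
    }
    return(get(name, envir = .ndcsi_registry, inherits = FALSE))
  }
  stopifnot(is.function(fn))
  assign(name, fn, envir = .ndcsi_registry)
  invisible(fn)
}

#' Normalized-difference canopy shadow index image
#'
#' Default formula (`"rededge_amplitude"`): the per-pixel red-edge amplitude
#' Dr — the maximum first derivative of reflectance in 680-750 nm — rescaled
#' scene-wise to `[0, 1]` by min-max over valid pixels. Shadows are
#' attenuated copies of the sunlit surface, so their derivative amplitude is
#' strictly smaller and the scaled index separates sunlit canopy (high) from
#' shadow (low). A scene where every pixel shares one spectrum has no
#' spread to scale and is an error.
#'
#' @param cube a [spectral_cube()].
#' @param formula registry key of the index definition.
#' @return an `index_image` with values in `[0, 1]`.
#' @export
ndcsi_image <- function(cube, formula = "rededge_amplitude") {
  stopifnot(inherits(cube, "spectral_cube"))
  if (max(cube$wavelengths) < 750 || min(cube$wavelengths) > 680) {
    stop("cube must cover the 680-750 nm red-edge window", call. = FALSE)
  }
  raw <- ndcsi_formula(formula)(cube)
  raw[cube$nodata_mask] <- NA_real_
  rng <- range(raw, na.rm = TRUE)
  if (!is.finite(diff(rng)) || diff(rng) < 1e-12) {
    stop("degenerate scene: red-edge amplitude has no spread to scale", call. = FALSE)
  }
  structure(list(values = (raw - rng[1]) / (rng[2] - rng[1]),
                 name = paste0("NDCSI[", formula, "]"),
                 source_wavelengths = cube$wavelengths[
                   cube$wavelengths >= 680 & cube$wavelengths <= 750]),
            class = "index_image")
}

# per-pixel max first derivative over 680-750 nm
.rededge_amplitude <- function(cube) {
  w <- cube$wavelengths
  nb <- length(w)
  inner <- which(w >= 680 & w <= 750)
  d <- dim(cube$reflectance)
  out <- matrix(-Inf, d[1], d[2])
  for (b in inner) {
    lo <- max(b - 1L, 1L); hi <- min(b + 1L, nb)
    db <- (cube$reflectance[, , hi] - cube$reflectance[, , lo]) / (w[hi] - w[lo])
    out <- pmax(out, db)
  }
  out
}

#' Segmentation thresholds
#' @param ndvi NDVI threshold (soil below), default 0.65.
#' @param ndcsi NDCSI threshold (shadow below), default 0.45.
#' @return a `threshold_pair`.
#' @export
threshold_pair <- function(ndvi = 0.65, ndcsi = 0.45) {
  if (ndvi <= -1 || ndvi >= 1) stop("ndvi threshold must lie in (-1, 1)", call. = FALSE)
  if (ndcsi <= 0 || ndcsi >= 1) stop("ndcsi threshold must lie in (0, 1)", call. = FALSE)
  structure(list(ndvi = ndvi, ndcsi = ndcsi), class = "threshold_pair")
}

#' Select a threshold at the intersection of two class histograms
#'
#' Bins both samples over their joint range, then takes the bin centre where
#' the two count curves cross between the class modes — the classical
#' histogram-intersection rule for separating two ground-object distributions.
#' Disjoint supports fall back to the midpoint of the gap; among multiple
#' crossings the one nearest the midpoint of the class means wins.
#'
#' @param values_a,values_b index values sampled from the two classes.
#' @param n_bins shared bin count over the joint range.
#' @return threshold value.
#' @export
histogram_intersection_threshold <- function(values_a, values_b, n_bins = 100) {
  a <- values_a[is.finite(values_a)]
  b <- values_b[is.finite(values_b)]
  if (!length(a) || !length(b)) stop("both classes need values", call. = FALSE)
  if (length(a) == length(b) && isTRUE(all.equal(sort(a), sort(b)))) {
    stop("class distributions are identical; no discriminating crossing", call. = FALSE)
  }
  # orient so class a has the smaller mean
  if (mean(a) > mean(b)) { tmp <- a; a <- b; b <- tmp }
  mid_means <- (mean(a) + mean(b)) / 2
  if (max(a) < min(b)) return((max(a) + min(b)) / 2)

  lo <- min(a, b); hi <- max(a, b)
  breaks <- seq(lo, hi, length.out = n_bins + 1)
  centres <- (breaks[-1] + breaks[-length(breaks)]) / 2
  bin_of <- function(x) pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE), 1L), n_bins)
  ca <- tabulate(bin_of(a), nbins = n_bins)
  cb <- tabulate(bin_of(b), nbins = n_bins)
  ma <- which.max(ca); mb <- which.max(cb)
  lo_bin <- min(ma, mb); hi_bin <- max(ma, mb)
  if (lo_bin == hi_bin) stop("class modes coincide; no discriminating crossing", call. = FALSE)
  d <- ca - cb
  cand <- integer(0)
  for (i in lo_bin:(hi_bin - 1)) {
    if (d[i] == 0) cand <- c(cand, i)
    else if (sign(d[i]) != sign(d[i + 1]) && d[i + 1] != 0) {
      cand <- c(cand, if (abs(d[i]) <= abs(d[i + 1])) i else i + 1L)
    }
  }
  if (d[hi_bin] == 0) cand <- c(cand, hi_bin)
  if (!length(cand)) {
    # no crossing between the modes (heavily overlapping histograms): fall
    # back to the bin boundary minimizing misclassification, ties toward the
    # midpoint of the class means
    mis <- vapply(seq_len(n_bins - 1), function(i) {
      sum(a > breaks[i + 1]) + sum(b <= breaks[i + 1])
    }, numeric(1))
    best <- which(mis == min(mis))
    edge <- breaks[best + 1]
    return(edge[which.min(abs(edge - mid_means))])
  }
  cand <- unique(cand)
  centres[cand][which.min(abs(centres[cand] - mid_means))]
}

#' Classify pixels into canopy, soil and shadow
#'
#' Sequential masking: soil wherever NDVI falls below the NDVI threshold;
#' among the remaining pixels, shadow wherever NDCSI falls below the NDCSI
#' threshold; the remainder is canopy. Nodata pixels propagate as nodata.
#' The soil-before-shadow order is part of the contract.
#'
#' @param cube a [spectral_cube()].
#' @param thresholds a [threshold_pair()].
#' @param ndvi_bands named vector `c(red =, nir =)` in nm.
#' @param ndcsi_formula NDCSI registry key.
#' @return a [class_mask()] with attribute `thresholds`.
#' @export
classify_pixels <- function(cube, thresholds = threshold_pair(),
                            ndvi_bands = c(red = 662, nir = 782),
                            ndcsi_formula = "rededge_amplitude") {
  stopifnot(inherits(cube, "spectral_cube"), inherits(thresholds, "threshold_pair"))
  ndvi <- ndvi_image(cube, red = ndvi_bands[["red"]], nir = ndvi_bands[["nir"]])$values
  ndcsi <- ndcsi_image(cube, formula = ndcsi_formula)$values
  labels <- matrix(1L, nrow(ndvi), ncol(ndvi))          # canopy
  labels[ndcsi < thresholds$ndcsi] <- 3L                # shadow
  labels[ndvi < thresholds$ndvi] <- 2L                  # soil masked first
  labels[cube$nodata_mask | is.na(ndvi) | (is.na(ndcsi) & labels != 2L)] <- 0L
  out <- class_mask(labels)
  attr(out, "thresholds") <- thresholds
  out
}

#' Score a segmentation against reference labels
#'
#' Builds the 3-class confusion table (rows = truth, columns = predicted) at
#' the supplied sample points, or over all pixels labelled in both masks,
#' and reports overall accuracy (trace/total), Cohen's kappa from the
#' marginal products, and the canopy overlap fractions
#' |A .and. B| / |canopy in each mask|.
#'
#' @param predicted,truth [class_mask()] objects of the same shape.
#' @param sample_points optional `data.frame(row, col)` of 0-based points.
#' @return a `segmentation_report` list.
#' @export
segmentation_accuracy <- function(predicted, truth, sample_points = NULL) {
  stopifnot(inherits(predicted, "class_mask"), inherits(truth, "class_mask"))
  if (!all(dim(predicted$labels) == dim(truth$labels))) {
    stop("masks must share shape", call. = FALSE)
  }
  if (is.null(sample_points)) {
    keep <- predicted$labels > 0L & truth$labels > 0L
    p <- predicted$labels[keep]; t_ <- truth$labels[keep]
  } else {
    i <- as.integer(sample_points$row) + 1L
    j <- as.integer(sample_points$col) + 1L
    if (any(i < 1 | i > nrow(truth$labels) | j < 1 | j > ncol(truth$labels))) {
      stop("sample points outside image", call. = FALSE)
    }
    lin <- cbind(i, j)
    p <- predicted$labels[lin]; t_ <- truth$labels[lin]
    keep <- p > 0L & t_ > 0L
    p <- p[keep]; t_ <- t_[keep]
  }
  if (!length(p)) stop("no valid points to score", call. = FALSE)
  cls <- 1:3
  confusion <- table(factor(t_, levels = cls, labels = c("canopy", "soil", "shadow")),
                     factor(p, levels = cls, labels = c("canopy", "soil", "shadow")))
  total <- sum(confusion)
  oa <- sum(diag(confusion)) / total
  pe <- sum(rowSums(confusion) * colSums(confusion)) / total^2
  kappa <- if (abs(1 - pe) < 1e-15) 1 else (oa - pe) / (1 - pe)
  inter <- sum(p == 1L & t_ == 1L)
  structure(list(
    overall_accuracy = oa,
    kappa = kappa,
    overlap_fraction_a_in_b = if (sum(p == 1L) > 0) inter / sum(p == 1L) else NA_real_,
    overlap_fraction_b_in_a = if (sum(t_ == 1L) > 0) inter / sum(t_ == 1L) else NA_real_,
    confusion = confusion,
    n = total
  ), class = "segmentation_report")
}

#' @export
print.segmentation_report <- function(x, ...) {
  cat(sprintf("<segmentation_report> OA = %.4f, kappa = %.4f (n = %d)\n",
              x$overall_accuracy, x$kappa, x$n))
  print(x$confusion)
  invisible(x)
}
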