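# Canopy spectra and the spectral parameters used for nitrogen inversion:
# five published vegetation indices, the first derivative, and the seven
# red-edge parameters (REP, Dr, Drmin, NDDr, RDr, DDr, SDr).

#' Construct a spectrum
#' @param reflectance unitless reflectance values.
#' @param wavelengths strictly increasing band wavelengths, nm.
#' @return an object of class `spectrum`.
#' @export
spectrum <- function(reflectance, wavelengths) {
  check_wavelengths(wavelengths)
  if (length(reflectance) != length(wavelengths)) {
    stop("reflectance and wavelengths must have equal length", call. = FALSE)
  }
  structure(list(reflectance = as.numeric(reflectance),
                 wavelengths = as.numeric(wavelengths)),
            class = "spectrum")
}

#' First derivative of a spectrum
#'
#' Central differences `(R[i+1] - R[i-1]) / (lambda[i+1] - lambda[i-1])` at
#' interior bands, one-sided differences at the two ends. Exact for linear
#' spectra everywhere and for quadratics at interior bands. Units: per nm.
#'
#' @param s a [spectrum()] with at least 3 bands.
#' @return an object of class `deriv_spectrum` (fields `derivative`,
#'   `wavelengths`).
#' @export
first_derivative <- function(s) {
  stopifnot(inherits(s, "spectrum"))
  n <- length(s$wavelengths)
  if (n < 3) stop("first derivative needs at least 3 bands", call. = FALSE)
  r <- s$reflectance; w <- s$wavelengths
  d <- numeric(n)
  d[1] <- (r[2] - r[1]) / (w[2] - w[1])
  d[n] <- (r[n] - r[n - 1]) / (w[n] - w[n - 1])
  i <- 2:(n - 1)
  d[i] <- (r[i + 1] - r[i - 1]) / (w[i + 1] - w[i - 1])
  structure(list(derivative = d, wavelengths = w), class = "deriv_spectrum")
}

#' Mean canopy spectrum over a circular ROI
#'
#' Averages (unweighted) the spectra of canopy-labelled pixels within the ROI
#' disc centred at the given 0-based (row, col). The number of contributing
#' pixels is attached as attribute `pixel_count`.
#'
#' @param cube a [spectral_cube()].
#' @param mask a [class_mask()] paired with `cube`.
#' @param row,col 0-based ROI centre.
#' @param radius ROI radius, pixels.
#' @param tree_id optional ID used in the error message when the ROI contains
#'   no canopy pixels.
#' @return a [spectrum()].
#' @export
roi_mean_spectrum <- function(cube, mask, row, col, radius, tree_id = NULL) {
  stopifnot(inherits(cube, "spectral_cube"), inherits(mask, "class_mask"))
  d <- dim(cube$reflectance)
  if (!all(dim(mask$labels) == d[1:2])) {
    stop("mask and cube shapes differ", call. = FALSE)
  }
  rr <- matrix(seq_len(d[1]) - 1L, d[1], d[2])
  cc <- matrix(rep(seq_len(d[2]) - 1L, each = d[1]), d[1], d[2])
  sel <- ((rr - row)^2 + (cc - col)^2 <= radius^2) & mask$labels == 1L
  npix <- sum(sel)
  if (npix == 0) {
    stop(sprintf("ROI%s at (%.0f, %.0f) contains no canopy pixels",
                 if (is.null(tree_id)) "" else paste0(" of tree ", tree_id),
                 row, col), call. = FALSE)
  }
  idx <- which(sel)
  nb <- d[3]
  m <- vapply(seq_len(nb), function(b) {
    mean(cube$reflectance[(b - 1L) * d[1] * d[2] + idx])
  }, numeric(1))
  out <- spectrum(m, cube$wavelengths)
  attr(out, "pixel_count") <- npix
  out
}

#' Published vegetation indices for nitrogen estimation
#'
#' Computes mSR705, mND705, CI_rededge, CI_green and DCNI from a single
#' spectrum, resolving each named wavelength to the nearest band (within
#' `tol` nm; the default 6 nm lets the canonical 445 nm term map to the
#' 450 nm band on a grid that starts there). Formulas are applied exactly as
#' published, with `variant = "printed"`:
#' \itemize{
#'   \item mSR705 = (R750 - R445) / (R705 - R445)
#'   \item mND705 = (R750 - R705) / (R750 + R705 - 2 R445)
#'   \item CI_rededge = (R840 - R870) / (R720 - R730) - 1
#'   \item CI_green = (R840 - R870) / R550 - 1
#'   \item DCNI = ((R722 - R702) / (R702 - R670)) / (R722 - R670 + 0.03)
#' }
#' The printed CI forms use band differences where the chlorophyll-index
#' literature uses sums; `variant = "literature"` substitutes
#' `(R840 + R870)` and `(R720 + R730)` band means. Division by zero yields
#' `NA`, never an error.
#'
#' @param s a [spectrum()].
#' @param variant `"printed"` (default) or `"literature"`.
#' @param tol nearest-band tolerance, nm.
#' @return named list of the five index values (class `vi_values`).
#' @export
vegetation_indices <- function(s, variant = c("printed", "literature"), tol = 6) {
  stopifnot(inherits(s, "spectrum"))
  variant <- match.arg(variant)
  R <- function(nm) s$reflectance[resolve_wavelength(nm, s$wavelengths, tol = tol)]
  r445 <- R(445); r550 <- R(550); r670 <- R(670); r702 <- R(702)
  r705 <- R(705); r720 <- R(720); r722 <- R(722); r730 <- R(730)
  r750 <- R(750); r840 <- R(840); r870 <- R(870)
  nir <- if (variant == "printed") r840 - r870 else (r840 + r870) / 2
  re  <- if (variant == "printed") r720 - r730 else (r720 + r730) / 2
  out <- list(
    mSR705 = safe_div(r750 - r445, r705 - r445),
    mND705 = safe_div(r750 - r705, r750 + r705 - 2 * r445),
    CI_rededge = safe_div(nir, re) - 1,
    CI_green = safe_div(nir, r550) - 1,
    DCNI = safe_div(safe_div(r722 - r702, r702 - r670), r722 - r670 + 0.03)
  )
  structure(out, class = "vi_values", variant = variant)
}

#' Red-edge parameters from a derivative spectrum
#'
#' Over the red-edge window (default 680-750 nm):
#' REP is the wavelength of the maximum first derivative (ties resolved to
#' the smallest wavelength), Dr that maximum value, Drmin the minimum
#' derivative value in the window, NDDr = (Dr - Drmin)/(Dr + Drmin),
#' RDr = Dr/Drmin, DDr = Dr - Drmin, and SDr the integral of the derivative
#' over the window (trapezoidal by default; a raw grid sum is selectable for
#' comparability with sum-based conventions).
#'
#' @param d a [first_derivative()] result.
#' @param window red-edge window endpoints, nm.
#' @param sdr_method `"trapezoid"` (default) or `"sum"`.
#' @return a list of class `red_edge_params`.
#' @export
red_edge_parameters <- function(d, window = c(680, 750),
                                sdr_method = c("trapezoid", "sum")) {
  stopifnot(inherits(d, "deriv_spectrum"))
  sdr_method <- match.arg(sdr_method)
  idx <- which(d$wavelengths >= window[1] & d$wavelengths <= window[2])
  if (length(idx) < 2) stop("red-edge window contains fewer than 2 bands", call. = FALSE)
  w <- d$wavelengths[idx]; v <- d$derivative[idx]
  imax <- which.max(v)  # first maximum = smallest wavelength on ties
  dr <- v[imax]; drmin <- min(v)
  sdr <- if (sdr_method == "trapezoid") {
    sum(diff(w) * (v[-1] + v[-length(v)]) / 2)
  } else {
    sum(v)
  }
  structure(list(
    REP = w[imax], Dr = dr, Drmin = drmin,
    NDDr = safe_div(dr - drmin, dr + drmin),
    RDr = safe_div(dr, drmin),
    DDr = dr - drmin,
    SDr = sdr
  ), class = "red_edge_params", window = window, sdr_method = sdr_method)
}

# ---- vectorized features over many spectra ---------------------------------

#' Describe the features a model consumes
#'
#' A feature specification names the two-band indices (type plus band pair)
#' and red-edge parameters that make up a model's input columns; the same
#' spec drives per-tree feature tables and per-pixel map prediction.
#'
#' @param two_band `data.frame` with columns `index_type` (NDSI/RSI/DSI),
#'   `lambda_i`, `lambda_j` (nm), or `NULL`.
#' @param red_edge character vector among `"REP"`, `"Dr"`, `"Drmin"`,
#'   `"NDDr"`, `"RDr"`, `"DDr"`, `"SDr"`, or `NULL`.
#' @return a `feature_spec` list.
#' @export
feature_spec <- function(two_band = NULL, red_edge = NULL) {
  if (!is.null(two_band)) {
    stopifnot(all(c("index_type", "lambda_i", "lambda_j") %in% names(two_band)),
              all(two_band$index_type %in% c("NDSI", "RSI", "DSI")))
  }
  if (!is.null(red_edge)) {
    stopifnot(all(red_edge %in% c("REP", "Dr", "Drmin", "NDDr", "RDr", "DDr", "SDr")))
  }
  structure(list(two_band = two_band, red_edge = red_edge), class = "feature_spec")
}

#' Compute a feature matrix for many spectra at once
#'
#' Rows of `R` are spectra on a shared wavelength grid (ROI means or raw
#' pixels); columns of the result are the features named by `spec`, in order:
#' two-band indices (named e.g. `NDSI_662_782`) then red-edge parameters.
#'
#' @param R numeric matrix `[spectra x bands]`.
#' @param wavelengths band grid, nm.
#' @param spec a [feature_spec()].
#' @param window red-edge window, nm.
#' @return numeric matrix `[spectra x features]` with column names.
#' @export
compute_feature_matrix <- function(R, wavelengths, spec, window = c(680, 750)) {
  stopifnot(is.matrix(R), ncol(R) == length(wavelengths),
            inherits(spec, "feature_spec"))
  cols <- list()
  if (!is.null(spec$two_band)) {
    for (k in seq_len(nrow(spec$two_band))) {
      ty <- spec$two_band$index_type[k]
      i <- resolve_wavelength(spec$two_band$lambda_i[k], wavelengths)
      j <- resolve_wavelength(spec$two_band$lambda_j[k], wavelengths)
      v <- two_band_index(R[, i], R[, j], ty)
      cols[[sprintf("%s_%d_%d", ty, round(wavelengths[i]), round(wavelengths[j]))]] <- v
    }
  }
  if (!is.null(spec$red_edge) && length(spec$red_edge)) {
    n <- nrow(R); nb <- ncol(R); w <- wavelengths
    D <- matrix(0, n, nb)
    D[, 1] <- (R[, 2] - R[, 1]) / (w[2] - w[1])
    D[, nb] <- (R[, nb] - R[, nb - 1]) / (w[nb] - w[nb - 1])
    if (nb > 2) {
      i <- 2:(nb - 1)
      D[, i] <- (R[, i + 1, drop = FALSE] - R[, i - 1, drop = FALSE]) /
        rep(w[i + 1] - w[i - 1], each = n)
    }
    idx <- which(w >= window[1] & w <= window[2])
    V <- D[, idx, drop = FALSE]
    imax <- max.col(V, ties.method = "first")
    dr <- V[cbind(seq_len(n), imax)]
    drmin <- do.call(pmin, as.data.frame(V))
    ww <- w[idx]
    tw <- numeric(length(ww))  # trapezoid weights
    dw <- diff(ww)
    tw[1] <- dw[1] / 2; tw[length(ww)] <- dw[length(dw)] / 2
    if (length(ww) > 2) tw[2:(length(ww) - 1)] <- (dw[-length(dw)] + dw[-1]) / 2
    vals <- list(REP = ww[imax], Dr = dr, Drmin = drmin,
                 NDDr = safe_div(dr - drmin, dr + drmin),
                 RDr = safe_div(dr, drmin),
                 DDr = dr - drmin,
                 SDr = as.numeric(V %*% tw))
    for (nm in spec$red_edge) cols[[nm]] <- vals[[nm]]
  }
  if (!length(cols)) stop("feature spec names no features", call. = FALSE)
  do.call(cbind, cols)
}
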