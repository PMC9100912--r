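# Exhaustive two-band spectral index screening: construct NDSI, RSI and DSI
# over every ordered band pair, correlate each index with canopy nitrogen,
# and select the most sensitive pairs above a correlation floor.

#' Two-band spectral index values
#'
#' NDSI = (Ri - Rj)/(Ri + Rj), RSI = Ri/Rj, DSI = Ri - Rj. Division by a
#' vanishing denominator yields `NA`.
#'
#' @param Ri,Rj reflectance vectors at the two bands.
#' @param index_type one of `"NDSI"`, `"RSI"`, `"DSI"`.
#' @return numeric vector of index values.
#' @export
two_band_index <- function(Ri, Rj, index_type = c("NDSI", "RSI", "DSI")) {
  index_type <- match.arg(index_type)
  switch(index_type,
         NDSI = safe_div(Ri - Rj, Ri + Rj),
         RSI = safe_div(Ri, Rj),
         DSI = Ri - Rj)
}

#' Correlation of every two-band index with nitrogen
#'
#' For every ordered band pair (i, j), i != j, computes the chosen index
#' across samples and its Pearson correlation with `y`. Ordered pairs are
#' materialized in full (RSI is not antisymmetric). Samples where an index
#' is undefined are excluded pairwise when they are under 5% of the sample;
#' beyond that the pair is invalidated (`NA`).
#'
#' @param spectra numeric matrix `[samples x bands]` of reflectance.
#' @param wavelengths band grid, nm.
#' @param y nitrogen concentrations, % (non-constant, length = samples).
#' @param index_type `"NDSI"`, `"RSI"` or `"DSI"`.
#' @param max_missing_frac invalidation threshold for undefined samples.
#' @return a `pair_correlation_map`: list with `r` (bands x bands matrix,
#'   rows = lambda_i, cols = lambda_j, diagonal `NA`), `wavelengths`,
#'   `index_type`, `n`.
#' @export
pairwise_correlation_map <- function(spectra, wavelengths, y,
                                     index_type = c("NDSI", "RSI", "DSI"),
                                     max_missing_frac = 0.05) {
  index_type <- match.arg(index_type)
  stopifnot(is.matrix(spectra), ncol(spectra) == length(wavelengths))
  n <- nrow(spectra)
  if (n < 3) stop("need at least 3 samples", call. = FALSE)
  if (length(y) != n) stop("y length must match the sample count", call. = FALSE)
  if (stats::sd(y) == 0) stop("y is constant; correlation undefined", call. = FALSE)
  nb <- ncol(spectra)
  r <- matrix(NA_real_, nb, nb,
              dimnames = list(lambda_i = wavelengths, lambda_j = wavelengths))
  for (i in seq_len(nb)) {
    M <- switch(index_type,
                NDSI = safe_div(spectra[, i] - spectra, spectra[, i] + spectra),
                RSI = safe_div(spectra[, i], spectra),
                DSI = spectra[, i] - spectra)
    n_na <- colSums(is.na(M))
    suppressWarnings(
      ri <- as.numeric(stats::cor(M, y, use = "pairwise.complete.obs"))
    )
    ri[n_na / n > max_missing_frac] <- NA_real_
    ri[i] <- NA_real_
    r[i, ] <- ri
  }
  if (all(is.na(r))) {
    stop("every band pair is undefined or zero-variance; cannot screen", call. = FALSE)
  }
  structure(list(r = r, wavelengths = as.numeric(wavelengths),
                 index_type = index_type, n = n),
            class = "pair_correlation_map")
}

#' @export
print.pair_correlation_map <- function(x, ...) {
  best <- which(abs(x$r) == max(abs(x$r), na.rm = TRUE), arr.ind = TRUE)[1, ]
  cat(sprintf("<pair_correlation_map> %s, %d bands, n = %d; max |r| = %.3f at (%g, %g) nm\n",
              x$index_type, length(x$wavelengths), x$n,
              abs(x$r[best[1], best[2]]),
              x$wavelengths[best[1]], x$wavelengths[best[2]]))
  invisible(x)
}

#' Select the most nitrogen-sensitive band pairs
#'
#' Filters pairs with |r| above the correlation floor (default 0.45, the
#' conventional screening cut for these indices), ranks by |r| descending
#' with ties broken toward the smaller `lambda_i` then `lambda_j`, and keeps
#' the top `top_k` per index type.
#'
#' @param maps list of `pair_correlation_map` objects (one per index type).
#' @param r_floor minimum |r| retained.
#' @param top_k pairs kept per index type.
#' @return `data.frame` with columns `index_type`, `lambda_i`, `lambda_j`, `r`.
#' @export
select_sensitive_pairs <- function(maps, r_floor = 0.45, top_k = 1) {
  if (inherits(maps, "pair_correlation_map")) maps <- list(maps)
  out <- do.call(rbind, lapply(maps, function(m) {
    stopifnot(inherits(m, "pair_correlation_map"))
    idx <- which(is.finite(m$r) & abs(m$r) > r_floor, arr.ind = TRUE)
    if (!nrow(idx)) return(NULL)
    df <- data.frame(index_type = m$index_type,
                     lambda_i = m$wavelengths[idx[, 1]],
                     lambda_j = m$wavelengths[idx[, 2]],
                     r = m$r[idx])
    df <- df[order(-abs(df$r), df$lambda_i, df$lambda_j), ]
    utils::head(df, top_k)
  }))
  if (is.null(out) || !nrow(out)) {
    stop(sprintf("no band pair exceeds |r| > %.2f", r_floor), call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Two-sided significance of a Pearson correlation
#'
#' p-value from the t-distribution on `r` with `n - 2` degrees of freedom;
#' reporting-only companion to the screening tables.
#'
#' @param r Pearson correlation.
#' @param n sample count.
#' @return p-value.
#' @export
correlation_p_value <- function(r, n) {
  stopifnot(n > 2)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(-abs(tstat), df = n - 2)
}
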