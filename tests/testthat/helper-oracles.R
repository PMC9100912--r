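# Independent oracles and small fixture builders used across test files.

# Brute-force two-band correlation map: plain double loop over ordered band
# pairs, stats::cor per cell. Deliberately naive and independent of the
# vectorized implementation it checks.
brute_pair_map <- function(spectra, wavelengths, y, index_type) {
  nb <- ncol(spectra)
  r <- matrix(NA_real_, nb, nb)
  for (i in seq_len(nb)) {
    for (j in seq_len(nb)) {
      if (i == j) next
      v <- switch(index_type,
                  NDSI = (spectra[, i] - spectra[, j]) / (spectra[, i] + spectra[, j]),
                  RSI = spectra[, i] / spectra[, j],
                  DSI = spectra[, i] - spectra[, j])
      v[!is.finite(v)] <- NA
      ok <- !is.na(v)
      if (sum(!ok) / length(v) > 0.05) next
      if (stats::sd(v[ok]) == 0) next
      r[i, j] <- stats::cor(v[ok], y[ok])
    }
  }
  r
}

# Exhaustive misclassification-minimizing threshold over candidate edges,
# lower-mean class assigned below the edge; ties (e.g. an empty gap between
# the classes) resolved toward the midpoint of the class means.
brute_threshold_scan <- function(a, b, n_bins = 100) {
  if (mean(a) > mean(b)) { tmp <- a; a <- b; b <- tmp }
  edges <- seq(min(a, b), max(a, b), length.out = n_bins + 1)
  mis <- vapply(edges, function(e) sum(a > e) + sum(b <= e), numeric(1))
  best <- edges[mis == min(mis)]
  best[which.min(abs(best - (mean(a) + mean(b)) / 2))]
}

# A reflectance spectrum on an arbitrary grid from named band values,
# e.g. toy_spectrum(c(`445` = 0.05, `550` = 0.12)).
toy_spectrum <- function(named_values) {
  wl <- as.numeric(names(named_values))
  spectrum(as.numeric(named_values)[order(wl)], sort(wl))
}

# Small random cube with float32-representable values (so ENVI round trips
# are bit-exact).
random_cube <- function(nr, nc, wavelengths, seed = 1) {
  set.seed(seed)
  vals <- sample(0:1000, nr * nc * length(wavelengths), replace = TRUE) / 1024
  spectral_cube(array(vals, dim = c(nr, nc, length(wavelengths))), wavelengths)
}

default_grid <- seq(450, 950, by = 4)
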