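# Internal helpers shared across modules.

#' Resolve a requested wavelength to the nearest band index
#'
#' Sensor grids rarely contain the exact wavelength a published index names,
#' so requests are snapped to the nearest band. By default the request must
#' lie within half a grid step of a band; callers that knowingly reference
#' wavelengths just outside the grid (e.g. the canonical 445 nm term on a
#' grid starting at 450 nm) may widen `tol`.
#'
#' @param wl requested wavelength in nm.
#' @param wavelengths strictly increasing band-centre wavelengths in nm.
#' @param tol maximum |request - band| accepted, nm; default half a step.
#' @return integer band index into `wavelengths`.
#' @keywords internal
resolve_wavelength <- function(wl, wavelengths, tol = NULL) {
  stopifnot(length(wavelengths) >= 1, length(wl) == 1, is.finite(wl))
  step <- if (length(wavelengths) > 1) stats::median(diff(wavelengths)) else Inf
  if (is.null(tol)) tol <- step / 2 + 1e-9
  idx <- which.min(abs(wavelengths - wl))
  if (abs(wavelengths[idx] - wl) > tol) {
    stop(sprintf("wavelength %.1f nm is more than %.2f nm from any band (grid %.0f-%.0f nm)",
                 wl, tol, min(wavelengths), max(wavelengths)), call. = FALSE)
  }
  idx
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. All stochastic operations in the package route
# through this so a single integer seed fully determines results.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Strictly increasing, finite wavelength grid?
check_wavelengths <- function(wavelengths) {
  if (length(wavelengths) < 1 || anyNA(wavelengths) || any(!is.finite(wavelengths))) {
    stop("wavelengths must be finite and non-empty", call. = FALSE)
  }
  if (length(wavelengths) > 1 && any(diff(wavelengths) <= 0)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  invisible(wavelengths)
}

# Division that returns NA instead of Inf/NaN when the denominator vanishes.
safe_div <- function(num, den, eps = 1e-12) {
  out <- num / den
  out[abs(den) < eps] <- NA_real_
  out
}
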