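# I/O boundary: hyperspectral cubes (ENVI-style BSQ float32), class masks
# (single-band 8-bit TIFF), and sample tables (CSV).
#
# Conventions: pixel coordinates in tables and function arguments are 0-based
# (row, col) with row 0 at the top, matching raster-file order; R's 1-based
# array indexing is an internal detail. Nodata in cubes is carried by a
# companion logical mask, never by sentinel reflectance values.

#' Construct a spectral cube
#'
#' A spectral cube is a rows x cols x bands reflectance array with a
#' wavelength axis. Reflectance is unitless surface reflectance; values up to
#' 1.2 are tolerated (calibration overshoot over bright targets).
#'
#' @param reflectance numeric array `[rows, cols, bands]`.
#' @param wavelengths strictly increasing band-centre wavelengths, nm.
#' @param nodata_mask optional logical matrix `[rows, cols]`; `TRUE` marks
#'   pixels with no valid data.
#' @return an object of class `spectral_cube`.
#' @export
spectral_cube <- function(reflectance, wavelengths, nodata_mask = NULL) {
  if (!is.array(reflectance) || length(dim(reflectance)) != 3) {
    stop("reflectance must be a 3-D array [rows, cols, bands]", call. = FALSE)
  }
  check_wavelengths(wavelengths)
  if (dim(reflectance)[3] != length(wavelengths)) {
    stop("third array dimension must match the number of wavelengths", call. = FALSE)
  }
  if (is.null(nodata_mask)) {
    nodata_mask <- matrix(FALSE, dim(reflectance)[1], dim(reflectance)[2])
  }
  stopifnot(is.logical(nodata_mask),
            all(dim(nodata_mask) == dim(reflectance)[1:2]))
  valid <- !nodata_mask
  if (any(valid)) {
    vals <- reflectance[rep(valid, times = length(wavelengths))]
    if (anyNA(vals) || any(!is.finite(vals))) {
      stop("reflectance must be finite at all valid pixels", call. = FALSE)
    }
    if (min(vals) < 0 || max(vals) > 1.2) {
      stop("reflectance outside [0, 1.2] at valid pixels", call. = FALSE)
    }
  }
  structure(list(reflectance = reflectance,
                 wavelengths = as.numeric(wavelengths),
                 nodata_mask = nodata_mask),
            class = "spectral_cube")
}

#' @export
dim.spectral_cube <- function(x) dim(x$reflectance)

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$reflectance)
  cat(sprintf("<spectral_cube> %d x %d pixels, %d bands (%.0f-%.0f nm)\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' Construct a class mask
#'
#' Per-pixel label raster over the legend 0 = nodata, 1 = canopy, 2 = soil,
#' 3 = shadow.
#'
#' @param labels integer matrix of legend values.
#' @return an object of class `class_mask`.
#' @export
class_mask <- function(labels) {
  if (!is.matrix(labels)) stop("labels must be a matrix", call. = FALSE)
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  if (!all(labels %in% 0:3)) {
    stop("class mask may only contain legend values 0 (nodata), 1 (canopy), 2 (soil), 3 (shadow)",
         call. = FALSE)
  }
  structure(list(labels = labels,
                 legend = c(nodata = 0L, canopy = 1L, soil = 2L, shadow = 3L)),
            class = "class_mask")
}

#' @export
print.class_mask <- function(x, ...) {
  tab <- table(factor(x$labels, levels = 0:3,
                      labels = names(x$legend)))
  cat("<class_mask>", nrow(x$labels), "x", ncol(x$labels), "pixels:\n")
  print(tab)
  invisible(x)
}

# ---- ENVI-style cube I/O ---------------------------------------------------
# Dialect: text header `<path>.hdr` + flat little-endian binary at `<path>`.
# Header keys: samples, lines, bands, data type (4 = 32-bit float),
# interleave (bsq), byte order (0), wavelength = { ... } in nm. Band-
# sequential layout, line-major within a band.

#' Write a spectral cube as ENVI-style BSQ float32
#'
#' @param cube a [spectral_cube()].
#' @param path binary file path; the header is written to `<path>.hdr`.
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path) {
  stopifnot(inherits(cube, "spectral_cube"))
  d <- dim(cube$reflectance)
  hdr <- c(
    "ENVI",
    "description = { hypercnc reflectance cube }",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 4",
    "interleave = bsq",
    "byte order = 0",
    "wavelength units = Nanometers",
    paste0("wavelength = { ",
           paste(format(cube$wavelengths, trim = TRUE, scientific = FALSE),
                 collapse = ", "), " }")
  )
  writeLines(hdr, paste0(path, ".hdr"))
  # [rows, cols, bands] -> sample-fastest, then line, then band (BSQ).
  vec <- as.vector(aperm(cube$reflectance, c(2, 1, 3)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(vec, con, size = 4, endian = "little")
  invisible(path)
}

#' Read an ENVI-style BSQ float32 cube
#'
#' Fails loudly on header/binary size mismatch, a missing wavelength list,
#' or a non-monotone wavelength grid.
#'
#' @param path binary file path written by [write_cube()] (header at
#'   `<path>.hdr`).
#' @return a [spectral_cube()].
#' @export
read_cube <- function(path) {
  hdr_path <- paste0(path, ".hdr")
  if (!file.exists(hdr_path)) stop("missing ENVI header: ", hdr_path, call. = FALSE)
  if (!file.exists(path)) stop("missing cube binary: ", path, call. = FALSE)
  hdr <- paste(readLines(hdr_path, warn = FALSE), collapse = "\n")

  grab_int <- function(key) {
    m <- regmatches(hdr, regexec(paste0(key, "\\s*=\\s*(\\d+)"), hdr))[[1]]
    if (length(m) < 2) stop("ENVI header missing '", key, "'", call. = FALSE)
    as.integer(m[2])
  }
  samples <- grab_int("samples")
  lines <- grab_int("lines")
  bands <- grab_int("bands")
  dtype <- grab_int("data type")
  if (dtype != 4L) stop("unsupported ENVI data type ", dtype, " (only 4 = float32)", call. = FALSE)
  il <- regmatches(hdr, regexec("interleave\\s*=\\s*(\\w+)", hdr))[[1]]
  if (length(il) < 2 || tolower(il[2]) != "bsq") {
    stop("unsupported interleave (only bsq)", call. = FALSE)
  }
  wl_m <- regmatches(hdr, regexec("wavelength\\s*=\\s*\\{([^}]*)\\}", hdr))[[1]]
  if (length(wl_m) < 2) stop("ENVI header missing wavelength list", call. = FALSE)
  wavelengths <- as.numeric(strsplit(wl_m[2], "[,\\s]+")[[1]] |> (\(x) x[nzchar(x)])())
  if (length(wavelengths) != bands) {
    stop("wavelength list length does not match band count", call. = FALSE)
  }
  check_wavelengths(wavelengths)

  n_expected <- as.numeric(samples) * lines * bands
  sz <- file.info(path)$size
  if (sz != n_expected * 4) {
    stop(sprintf("cube binary size mismatch: %d bytes on disk, %d expected from header",
                 sz, n_expected * 4), call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  vec <- readBin(con, what = "numeric", n = n_expected, size = 4, endian = "little")
  arr <- aperm(array(vec, dim = c(samples, lines, bands)), c(2, 1, 3))
  spectral_cube(arr, wavelengths)
}

# ---- mask I/O --------------------------------------------------------------

#' Write a class mask as a single-band 8-bit TIFF
#' @param mask a [class_mask()].
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "class_mask"))
  tiff::writeTIFF(mask$labels / 255, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read a class mask from a single-band 8-bit TIFF
#' @param path `.tif` path written by [write_mask()].
#' @return a [class_mask()].
#' @export
read_mask <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(m)) == 3) m <- m[, , 1]
  class_mask(m)
}

# ---- sample tables ---------------------------------------------------------

#' Construct a sample table
#'
#' One row per sampled tree: its ID, crown-centre ROI (0-based pixel row/col
#' plus radius in pixels) and the measured nitrogen concentration in % of
#' dry mass.
#'
#' @param tree_id character vector of unique IDs.
#' @param row,col 0-based ROI centre coordinates, pixels.
#' @param radius_px ROI radius, pixels.
#' @param n_pct measured nitrogen concentration, %.
#' @return a `data.frame` with class `sample_table`.
#' @export
sample_table <- function(tree_id, row, col, radius_px, n_pct) {
  tree_id <- as.character(tree_id)
  df <- data.frame(tree_id = tree_id, row = as.numeric(row),
                   col = as.numeric(col), radius_px = as.numeric(radius_px),
                   n_pct = as.numeric(n_pct), stringsAsFactors = FALSE)
  dup <- tree_id[duplicated(tree_id)]
  if (length(dup)) {
    stop("duplicate tree_id: ", paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  if (nrow(df) && (anyNA(df$n_pct) || any(df$n_pct <= 0))) {
    stop("n_pct must be positive and numeric", call. = FALSE)
  }
  class(df) <- c("sample_table", "data.frame")
  df
}

#' Read a sample table from CSV
#'
#' Expects the header `tree_id,row,col,radius_px,n_pct`. An empty body is a
#' valid empty table; duplicate IDs and non-numeric nitrogen values are
#' rejected.
#'
#' @param path CSV path.
#' @return a [sample_table()].
#' @export
read_sample_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = list(tree_id = "character"))
  need <- c("tree_id", "row", "col", "radius_px", "n_pct")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("sample table missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (cc in c("row", "col", "radius_px", "n_pct")) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    if (nrow(df) && anyNA(v)) stop("non-numeric values in column ", cc, call. = FALSE)
    df[[cc]] <- v
  }
  sample_table(df$tree_id, df$row, df$col, df$radius_px, df$n_pct)
}

#' Write a sample table to CSV
#' @param table a [sample_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(table, path) {
  stopifnot(inherits(table, "sample_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
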