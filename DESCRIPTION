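Package: hypercnc
Title: Canopy Nitrogen Retrieval from Hyperspectral Orchard Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for retrieving apple canopy nitrogen
    concentration (CNC, percent of dry mass) from hyperspectral reflectance
    cubes. Segments canopy pixels from soil and shadow by sequential
    NDVI/NDCSI thresholding with histogram-intersection threshold selection,
    extracts region-of-interest mean spectra, computes vegetation indices and
    red-edge derivative parameters, screens exhaustive two-band spectral
    indices (NDSI, RSI, DSI) by correlation with nitrogen, fits univariate
    curve families, partial least squares regression and a small
    Levenberg-Marquardt-trained neural network, evaluates models with
    R-squared, RMSE and the ratio of performance to deviation (RPD), and
    renders per-pixel nitrogen maps. Includes a synthetic orchard scene
    generator with known class masks and nitrogen ground truth so the whole
    workflow is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    tiff,
    utils
Suggests:
    jsonlite,
    mixOmics,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
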