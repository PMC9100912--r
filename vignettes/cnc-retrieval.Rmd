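---
title: "Canopy nitrogen retrieval from hyperspectral orchard imagery: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Canopy nitrogen retrieval: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypercnc)
```

## The problem

Leaf nitrogen sets chlorophyll content, and chlorophyll leaves two
fingerprints on a canopy reflectance spectrum: deeper absorption in the red
(~660–680 nm) and a shift of the *red edge* — the steep reflectance rise
between the red trough and the near-infrared plateau — toward longer
wavelengths. An imaging spectrometer over an orchard therefore carries a
recoverable nitrogen signal, but an orchard scene is not wall-to-wall
canopy: bare inter-row soil and crown shadows occupy most pixels, and both
contaminate any spectrum averaged naively over a tree's surroundings. The
workflow in this package is the standard empirical-inversion chain for this
situation: mask the non-canopy pixels, average canopy spectra per tree,
derive spectral features, screen them against measured nitrogen, fit
regression models, and invert the best model back onto the image.

Everything below documents how each stage is defined here, which knobs it
has, and where a design decision was genuinely open.

## Segmentation

Classification is *sequential*: soil is removed first, shadow second, and
what remains is canopy.

* **Soil**: NDVI $=(R_{NIR}-R_{red})/(R_{NIR}+R_{red})$ below the NDVI
  threshold. Default bands are 662 nm (red) and 782 nm (NIR) — the red/NIR
  pair the package's own two-band screening typically finds most
  nitrogen-sensitive — and both are arguments, since NDVI itself is
  insensitive to the exact choice within those regions.
* **Shadow**: NDCSI below the NDCSI threshold, evaluated only on pixels
  that survived the soil mask. The NDCSI definition in the shadow-index
  literature could not be pinned to a single printed formula, so the index
  is a *registry entry* (`ndcsi_formula()`) users can override. The default
  is the per-pixel red-edge derivative amplitude (maximum first derivative
  in 680–750 nm), min–max scaled over the scene to $[0,1]$. The rationale:
  a shadow is, to first order, the same surface under less irradiance, so
  its spectrum is approximately a multiplicatively attenuated copy — the
  spectral *shape* (and hence NDVI) is preserved while every derivative
  shrinks by the attenuation factor. The derivative amplitude is therefore
  exactly the quantity shadow suppresses, while NDVI cannot see it.
* **Thresholds**: defaults 0.65 (NDVI) and 0.45 (NDCSI, on the scaled
  index — whether the conventional 0.45 refers to a scaled or raw index is
  ambiguous in the literature; scaled is assumed and documented).
  `histogram_intersection_threshold()` offers the classical data-driven
  alternative: bin two exemplar classes over their joint range (100 bins by
  default, which keeps crossings stable at the scene sizes used here) and
  take the bin centre where the count curves cross between the class modes.
  Degenerate cases are defined explicitly: disjoint supports give the
  midpoint of the gap; multiple crossings resolve toward the midpoint of
  the class means; identical distributions are an error. When the
  histograms overlap so heavily that no crossing exists between the modes,
  the function falls back to the misclassification-minimizing bin edge.

Accuracy is reported as overall accuracy, Cohen's kappa (expected agreement
from marginal products) and the canopy overlap fractions
$|A \cap B| / |A|$, $|A \cap B| / |B|$, over all mutually labelled pixels
or a supplied sample-point set.

## Spectral features

* **ROI spectra** are unweighted means over canopy-labelled pixels inside a
  disc (centre and radius in pixels, 0-based coordinates); the pixel count
  is recorded, and an ROI with no canopy pixels is an error naming the
  tree.
* **Derivatives** are central differences at interior bands and one-sided
  at the ends, in per-nm units — exact for linear spectra, and exact at
  interior bands for quadratics. No smoothing is applied anywhere: the
  derivative is computed on raw reflectance, so any pre-smoothing policy is
  the caller's responsibility.
* **Vegetation indices** are computed exactly as published, including two
  forms — $CI_{red-edge}=(R_{840}-R_{870})/(R_{720}-R_{730})-1$ and
  $CI_{green}=(R_{840}-R_{870})/R_{550}-1$ — whose numerators are band
  *differences* where the chlorophyll-index literature uses sums. The
  printed forms are the default (`variant = "printed"`); the sum-based
  literature forms are available as `variant = "literature"`. The intent of
  the original typesetting is not guessed. DCNI is parenthesized
  left-to-right as printed:
  $((R_{722}-R_{702})/(R_{702}-R_{670}))/(R_{722}-R_{670}+0.03)$.
  Named wavelengths snap to the nearest band within 6 nm — wide enough that
  the canonical 445 nm term resolves to the 450 nm band on a grid that
  starts there — while the two-band index operations stay strict at half a
  grid step. Division by zero yields `NA` sentinels, never exceptions, and
  sentinels are excluded pairwise downstream.
* **Red-edge parameters** use the window 680–750 nm (the REP convention;
  the "red-edge region" for SDr has no universal endpoints, so the same
  window is used). REP is the wavelength of the maximum derivative with
  ties resolved to the smallest wavelength; Dr that maximum; Drmin the
  minimum derivative *value* in the window — the value interpretation is
  the only one that type-checks inside NDDr, RDr and DDr, although some
  sources word Drmin as a wavelength. SDr is the trapezoidal integral of
  the derivative over the window, which unlike a raw grid sum is invariant
  to band spacing; a `"sum"` method is selectable for comparability.

## Two-band screening

All $126 \times 125$ ordered band pairs per index type are materialized —
ordered rather than upper-triangle because RSI is not antisymmetric — and
Pearson-correlated with nitrogen ("correlation coefficient" is taken as
Pearson). Undefined index values are excluded pairwise when under 5% of
samples; beyond that the pair is invalidated. Selection filters
$|r| > 0.45$ (the conventional sensitivity floor for these indices), ranks
by $|r|$ with ties broken toward the smaller first then second wavelength,
and keeps the top `top_k` per type. Significance stars are available via
the t-distribution on $r$ but are reporting-only. Screening uses all
samples; the modeling/validation split applies only at model fitting —
whether screening should itself be restricted to the modeling set is a
legitimate alternative, but with a fixed feature construction the
difference only matters for inference, not for the fitted models.

The implementation is vectorized per anchor band; the test suite and the
acceptance script hold it to within $10^{-12}$ of an independently coded
brute-force double loop over all cells.

## Sample splitting

Samples are sorted by nitrogen (ties by tree ID) and every 4th rank goes to
validation — 69/23 at $n = 92$. Two documented reconciliations: the source
convention describes this as "a ratio of 2:1" while reporting 69/23, which
is 3:1; the printed counts win, and a strict 2:1 (`pattern = 3`) remains
available. And when $n$ is divisible by 4 the top rank falls on the
validation cycle, which would put the sample maximum in the validation set
— contradicting the reference cohort statistics, where the modeling set
contains both extremes. The rule therefore swaps the top rank with its
neighbour, anchoring both extremes in the modeling set as rank-based
calibration splits conventionally do; validation nitrogen is then nested
inside the modeling range for any input.

## Models

* **Curve families**: linear, cubic and logarithmic fits are closed-form
  least squares; exponential $y = a e^{bx}$ and rational
  $y = a/(x^2+bx+c)$ are Levenberg–Marquardt nonlinear least squares
  (via `minpack.lm`) seeded from their linearizations (log-transform and
  inverse-y quadratic regression respectively). A rational fit whose
  denominator has a real root inside the observed $x$ range is rejected:
  a pole inside the prediction domain makes the model useless for
  inversion. Noise-free identifiability (coefficients recovered to
  $10^{-4}$ relative or better from data generated by each family) is part
  of the acceptance suite.
* **PLSR** is NIPALS on centred, unit-variance predictors and a centred
  response, with the regression vector rebuilt as
  $B = W(P'W)^{-1}q$. It is deterministic, reduces to OLS with one
  component on one feature, and equals multiple linear regression at full
  rank — both identities are tested, along with agreement with an
  independent PLS implementation.
* **Network**: architecture [features, 4, 1], tanh hidden layer, identity
  output. Inputs and target are min–max scaled to $[-1,1]$ to match the
  tanh range. Training is full-batch Levenberg–Marquardt on the analytic
  Jacobian: damping starts at 0.001, is multiplied by 10 on a rejected step
  and divided by 10 on an accepted one (the standard Marquardt policy; the
  source convention states only the initial value). Iterations cap at
  1000, training stops early when the scaled-target MSE reaches $10^{-4}$,
  and a random 15% internal validation split selects the retained weights
  ("best validation performance"; the fraction is this package's choice,
  as is using an internal split rather than the 23-sample verification
  set, which is kept strictly untouched for final evaluation). Initial
  weights are uniform on $[-0.5, 0.5]$. A single integer seed determines
  initialization and the internal split, so training is bit-reproducible;
  accepted-step training loss is non-increasing by construction. A
  constant target short-circuits to a constant predictor rather than
  training through a degenerate scaling.

## Evaluation

The metric definitions keep the printed conventions of the inversion
literature exactly, including their quirks: $R^2$ is the
regression-sum-of-squares form $\sum(\hat y_i-\bar y)^2/\sum(y_i-\bar y)^2$,
which can exceed 1 for biased predictors (the conventional $1-SSE/SST$ is a
flagged alternative); RMSE uses $1/N$ while SD uses $1/(N-1)$. One
consequence, verified analytically in the acceptance suite: the mean
predictor has $R^2 = 0$ and RPD $= \sqrt{N/(N-1)}$, i.e. 1.0225 at
$N = 23$ — RPD's floor is slightly above 1, not 1. RPD interpretation uses
strict cuts: below 1.4 unusable, above 2.0 superior, boundaries inclusive
to "moderate". A perfect prediction (RMSE = 0) flags `perfect` and leaves
RPD undefined rather than infinite.

## Mapping

Inversion is per-pixel, not per-ROI: each canopy pixel's own spectrum
yields the model's features and a prediction, which reproduces within-crown
gradients. For nonlinear models a per-ROI prediction would differ by a
Jensen gap — applying a nonlinear model to a mean spectrum is not the mean
of per-pixel predictions — so the per-ROI route is deliberately not the
default. Predictions clip to [1, 4]% N with the clip count recorded in the
map's provenance alongside the feature spec, thresholds and model seed.

## The synthetic scene: what it does and does not emulate

The generator exists because no imagery/assay pair for this problem is
publicly deposited. It emulates the features the workflow's logic depends
on:

* a 450–950 nm grid at 4 nm (126 bands);
* three classes — circular crowns on a regular planting grid, soil
  background, shadow discs offset from each crown — with exact ground-truth
  labels;
* per-tree nitrogen from a truncated normal, mean 2.622% N, SD 0.193%,
  bounds [1.5, 3.5]% chosen to bracket the reference cohort's observed
  2.121–3.119% range with margin;
* a monotone nitrogen → spectrum link: logistic red edge with inflection
  $700 + 12(N-2)$ nm, red reflectance decreasing in N, NIR plateau 0.50,
  a green reflectance bump at 550 nm and a chlorophyll absorption dip at
  670 nm that deepens with N; soil as an affine 0.15→0.30 ramp; shadow as
  the occluded crown's spectrum times an attenuation factor (default
  0.25), which preserves NDVI while shrinking the red-edge derivative —
  precisely the structure NDCSI masking exploits;
* i.i.d. Gaussian pixel noise (default SD 0.005 reflectance, a
  conservative figure for a calibrated snapshot sensor at these
  reflectance levels), clipped to (0, 1).

The coupling constants are documented stand-ins, not calibrated to any
cultivar; a radiative-transfer model (PROSPECT/SAIL), BRDF and illumination
geometry, within-crown physiological gradients, spatially correlated noise
and atmospheric residuals are all deliberately absent. Consequently a
passing pipeline on synthetic scenes demonstrates *correctness of the
machinery* — segmentation logic, feature arithmetic, search, fitting,
evaluation, mapping — and the *qualitative* recoverability of a
nitrogen-like signal. It does not certify field accuracy: on the synthetic
scenes the two-band correlations and validation RPDs are far higher than
any field campaign would produce, exactly because the scene is clean. The
quantitative contracts the package does assert (and tests) are arithmetic
identities, oracle equivalences, and recovery of its own planted
parameters.

Scene sizes in the tests and acceptance script (up to 400 × 400 pixels,
92 trees) were chosen so the whole suite exercises the full 126-band search
and a realistic cohort size while staying comfortable on a single CPU.

## Numerical conventions

* Wavelength resolution: nearest band within half a grid step (strict), 6 nm
  for the published-index wavelengths; requests farther away are errors.
* Division by (near-)zero anywhere in index arithmetic yields `NA`
  sentinels; readers validate invariants and fail loudly rather than
  coerce.
* ENVI cubes are BSQ, little-endian float32, sample-fastest; round trips
  are bit-exact for float32-representable values, and header/binary size
  mismatches are detected on read.
* All stochastic code paths (nitrogen draws, scene noise, network
  initialization and internal split) run under an explicit seed through a
  scoped RNG that never leaks state into the caller's session.

## Known limitations

* The NDCSI default is a stand-in definition (flagged above) — users
  reproducing a specific published segmentation should register the exact
  index formula of that source.
* The univariate curve families are fitted y-on-x with the feature as
  regressor; families with restricted domains (log, rational) refuse data
  that violate them rather than silently transforming.
* The network's LM solver forms the full normal-equations matrix, which is
  appropriate at this scale (tens of weights) and not intended for large
  architectures.
* Only BSQ/float32 cubes, single-band TIFF masks and RFC-4180 CSV tables
  are supported at the I/O boundary; georeferencing is out of scope.
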