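---
title: "Methods: colour-checker correction and pigment calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: colour-checker correction and pigment calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phytochroma)
```

This vignette documents the models, parameter choices and numerical
conventions behind `phytochroma`, and what its synthetic test scenes do
and do not demonstrate about real photographs.

## Working assumptions

The pipeline assumes photographs of plant material on a white background,
taken from directly above, containing an axis-aligned 24-swatch colour
checker and one object of known physical size placed as the left-most
object. Shadows are assumed absent (capture-time discipline), objects are
assumed non-touching, and the scene is assumed flat enough that one
mm-per-pixel scale per axis is adequate — no perspective or lens-geometry
correction is attempted.

## Flat-field correction

The background exposure is smoothed with a 5 × 5 arithmetic-mean (box)
kernel with replicated edges, then each channel is divided by its own
maximum so the field lies in (0, 1]; the experimental image is divided
elementwise by this field, clipped to [0, 255] and re-quantised. Choices
worth recording:

- **Box kernel.** A 5 × 5 mean filter is the minimal smoothing that
  suppresses sensor noise in the background shot without reshaping the
  vignette profile; its only job is to stop noise in one exposure being
  imprinted on another.
- **Per-channel normalisation.** Normalising each channel by its own
  maximum (rather than a shared maximum) preserves the white balance of
  the flat field: the correction removes *spatial* non-uniformity and
  leaves global colour cast to the colour-correction step.
- **Division guard.** Normalised field values below 1/255 are floored at
  1/255, so a dead background pixel yields an amplification of at most
  255× rather than infinity.
- **Quantisation.** All image arithmetic ends in clip-then-round;
  rounding is half-up (`floor(x + 0.5)`), chosen over banker's rounding
  so that repeated correction of an already-correct image is exactly
  idempotent.

## Checker detection, sampling and ordering

The card is found as the largest connected component of dark pixels (all
channels below 60 by default — the card frame is near-black while plant
material, in practice, is not dark in *all* channels simultaneously).
Two sanity checks reject non-cards: the component's bounding-box aspect
ratio must lie in [1.2, 1.8] (a 4 × 6 card is 1.5), and at least 90% of
the bounding-box perimeter must belong to the component — a rotated card
fails this trace test, and the error message says to crop/rotate or pass
an explicit corner `hint`. Border thickness is estimated as the shortest
dark run walking inward along the four mid-lines (capped at 20% of the
card's short side), and the interior is split into a 4 × 6 grid.

Each swatch is sampled as the mean RGB of the **central 50%** of its
cell, which keeps the estimate away from cell borders and printing
bleed. Orientation is resolved by evaluating the admissible axis-aligned
placements (portrait, portrait rotated 180°, landscape clockwise or
counter-clockwise) and keeping the one whose anchor-position cell best
matches the light-blue anchor colour — or, when a reference set is
supplied, the placement minimising total colour distance over all 24
swatches.

The package fixes a single ordering convention: the card in portrait,
4 columns × 6 rows, numbered down the columns, anchor swatch at position
19 (top-right). Reference CSVs must follow it. The bundled reference set
is **synthetic** — 24 distinct sRGB values spanning the gamut with a
six-step neutral ramp — and is what the scene renderer and the test
suite use; photographs of a real card need that card's own reference
values in the same order.

## Polynomial colour correction

Each output channel is an OLS fit of the reference swatch values on the
nine-term basis (R, G, B, R², G², B², R³, G³, B³) of the observed
values, with **no intercept** — the model class is exactly the nine-term
cubic. Channels are divided by 255 before powers are taken: on the 0–255
scale the cubic design matrix has condition numbers in the 10⁷ range,
on the unit scale it is well-conditioned; predictions are identical, so
this is purely a conditioning choice, and the stored coefficients are
tagged with their input scale. The per-channel
r² = 1 − SSR/SST (SST about the reference-channel mean) is the
"successfully correctable" diagnostic, with 0.95 as the working floor.
A rank-deficient design (e.g. all swatches equal) raises a
non-identifiability error rather than returning an arbitrary solution.

Because the basis contains the identity map, the fitted correction can
never have larger summed squared swatch error than no correction; the
test suite checks the stronger empirical property that the *mean* ΔRGB
over the 24 swatches decreases on every distorted scene it generates.

## Segmentation and measurement

Background pixels are those with **all three channels at or above the
threshold** (default 150). A conjunctive near-white test was chosen over
a grayscale threshold because plant material can be bright in one
channel (yellow fruit) while remaining clearly non-white. The mask is
cleaned by morphological opening then closing with a 5 × 5 elliptical
structuring element (one iteration each) and components below
`min_object_area` (default 500 px) are discarded; these defaults remove
isolated noise pixels without visibly eroding objects larger than a few
hundred pixels.

Objects are the connected components of the non-white mask, sorted
left-to-right by bounding-box x (ties by y), which makes the ordering a
deterministic total order and puts the known-size reference first when
the capture convention is followed. Component labelling operates
directly on the cleaned mask; edge-detector-plus-contour tracing would
find the same external boundaries on a white background, and labelling
gives the pixel-exact masks that the area measurements need. Touching
objects merge into one component — a deliberate, documented limitation
(no watershed splitting), mitigated at capture time.

Width and height are axis-aligned mask extents scaled by the per-axis
calibration (known size / pixel extent of the reference object); area is
the mask pixel count times the pixel area. Per-axis scales are kept
separate because the reference object provides both, and averaging them
would hide anisotropy instead of correcting it.

## Colour spaces

Mean object colour is averaged in sRGB-encoded values (not linear
light), matching how such pipelines conventionally report "mean RGB";
the pigment models are calibrated against colours computed the same way,
so the convention cancels out of predictions. YUV uses the BT.601
full-range matrix with +128 chroma offset (the dialect is not otherwise
pinned down by convention; full-range is what image libraries produce
for 8-bit stills), so achromatic colours map to U = V = 128 exactly.
CIELAB uses the standard sRGB decode → XYZ (D65) → Lab path with the 2°
observer; the implementation is checked against an independently
computed 1,000-point reference lattice at 0.05 absolute tolerance.

## Pigment models

Wet-chemistry ground truth: lycopene from absorbance at 503 nm in
hexane, L = A₅₀₃ × 31.2 / g tissue, where 31.2 is *recomputed* from the
molar extinction coefficient (17.2 × 10⁴ M⁻¹cm⁻¹), molar mass
(536.9 g/mol), the 10 ml hexane volume and unit conversions, and
asserted to 3 significant figures at every call — the constant cannot
silently drift from its derivation. Chlorophyll a/b from 80% acetone
extracts via C_a = 12.21A₆₆₃ − 2.81A₆₄₆ and C_b = 20.13A₆₄₆ − 5.03A₆₆₃,
with C_t their sum.

**Lycopene model** L = β₁e^(β₂·a\*/b\*) + β₃, fitted by
Levenberg–Marquardt with relative tolerances 10⁻¹⁰ and the solver's
iteration ceiling (1024). Starting values are data-driven: β₃ from
min(y); β₂ and β₁ from a log-linear regression of y − β₃ + ε on x, with
ε = 10⁻⁹ guarding the point that sits exactly at β₃. A constant
response is rejected as non-identifiable (β₂ is then unconstrained).
At least 4 points are required for the 3-parameter model.

**Chlorophyll model** C_t = e^(β₁R + β₂G + β₃B + β₄) is *exactly*
linear in log C_t, so it is fitted by a single OLS of log(ct) on
(R, G, B, 1) rather than iterative NLS. This changes the implied error
model from additive to multiplicative on the original scale — a
deliberate trade of one distributional assumption for an exact,
convergence-free fit; diagnostics (r², RMSE) are computed on the
original scale so they remain comparable. Non-positive responses and
rank-deficient designs (a constant channel) are rejected.

Predictions carry an `extrapolated` flag whenever the predictor leaves
the training range (per channel, for the RGB model): exponential
calibrations are only trustworthy inside the range they were fitted on,
and the flag makes silent extrapolation impossible. `validate_model()`
reports r² about the y = x line (which equals the fit diagnostic on
training data), the regression r² of predicted on observed (the two can
differ off the identity line; both are reported), RMSE, standardised
residuals and the predicted-on-observed ANOVA F, df and p.

### Parameter recovery conditions

The recovery tests use β = (5, 2, 10) over a\*/b\* ∈ [−0.5, 1.2] — a
green-through-red tomato span with lycopene roughly 12–65 mg/kg. On
noiseless data the fit recovers the parameters to within 0.1%. The
noisy-recovery test uses n = 20 points on an **evenly spaced** grid over
the range (how a calibration set is actually assembled: fruit selected
to span ripeness stages), noise SD = 5% of the response range, 200
replicates; mean bias is then ≈4% (β₁), <1% (β₂), ≈2% (β₃). Worth
knowing: with predictors drawn uniformly at random each replicate, the
amplitude β₁ shows ≈11% mean bias under the same noise — ordinary
finite-sample nonlinearity bias of exponential NLS, not a fitting
defect; it shrinks with n and with noise.

## The synthetic scene generator

`render_scene()` emulates the capture layout (card, reference square,
fruit-like discs on white) with **hard edges and no anti-aliasing**, so
every ground-truth pixel count is exact and truth manifests are
consistent with the image by construction. `apply_camera_distortion()`
applies, in a fixed documented order: a radial quadratic vignette (1 at
centre, 1 − strength at the farthest corner), a channelwise cubic cast
on the unit scale with no constant term (the same model class the
correction fits), then seeded additive Gaussian noise, then
clip-and-quantise. All stochastic operations take mandatory seeds and
restore the caller's RNG state.

The default test conditions — vignette strength 0.2, noise SD 2 (8-bit
units), casts with linear terms 0.85–0.95 and cubic terms up to ±0.12 —
represent a moderately miscalibrated consumer camera in uneven light.
The scenes are 640 × 480 with ~45 px swatch cells and discs of 30–40 px
radius; small enough that the full 20-scene error-reduction check runs
in well under a minute, large enough that cell sampling and morphology
behave as on real photographs.

What passing on these scenes does **not** show: robustness to
anti-aliased or blurred object edges, shadows, specular highlights,
perspective-distorted or rotated checkers, JPEG compression artefacts,
or casts outside the cubic model class (e.g. spatially varying white
balance). The cast-within-model-class condition in particular makes
near-perfect swatch recovery *expected*; real cameras leave residual
error (several ΔRGB units) because their response is not exactly a
channelwise cubic.

## Known limitations

- Touching objects are measured as one; there is no watershed split.
- Checker detection requires an axis-aligned card (or a corner hint);
  perspective distortion is out of scope.
- The YUV dialect and the sRGB-encoded averaging convention are fixed;
  pipelines using studio-range YUV or linear-light means will disagree
  by construction.
- Pigment model parameters are camera-specific: a model fitted on one
  camera's corrected colours must be refitted for another camera, and
  the extrapolation flag should be respected when applying any model.
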