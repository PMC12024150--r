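---
title: "Methods: marker-calibrated area measurement and area-weight modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: marker-calibrated area measurement and area-weight modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holoweigh)
```

## The estimation problem

Sea cucumbers lose water and contract when handled, so hand-weighing both
stresses the animal and biases the measurement. `holoweigh` implements a
non-invasive alternative: photograph the animal from above next to a printed
square fiducial marker of known physical side length, measure the animal's
projected dorsal ("top-view") area $x$ in cm$^2$ from the image, and convert
area to weight $y$ in grams through a species-specific allometric regression.
The marker solves the central metrological problem of single-camera imaging -
unknown and varying camera-to-subject distance - because its apparent side
length in pixels fixes the pixels-per-centimetre scale of each individual
image.

The pipeline has four stages, each usable on its own:

1. **Scale calibration** (`detect_marker()`, `compute_scale()`): find the
   marker, measure its four side lengths in pixels, and set
   $\mathrm{px/cm} = \overline{\ell}_{1..4} / s$ where $s$ is the printed
   side (default 10 cm).
2. **Segmentation and measurement** (`remove_background()`, `binarize()`,
   `mask_marker_region()`, `measure_objects()`): isolate the dark organism
   on its light background with Otsu's threshold, suppress the marker
   region, extract each object's external contour, and convert its pixel
   area to cm$^2$.
3. **Area-weight modelling** (`fit_weight_model()`, `select_best_model()`,
   `predict_weight()`): fit five candidate families and select by the
   coefficient of determination.
4. **Validation** (`percent_error()`, `validate_weights()`): compare
   estimated with hand-weighed values via absolute percent error and an
   assumption-checked independent two-sample *t* test.

A synthetic-scene generator (`scene_spec()`, `render_scene()`) produces test
images with exact ground truth, so all of the above is verifiable without any
photograph.

## The regression families

With $x$ the top-view area (cm$^2$) and $y$ the weight (g), the five
families are

| family | equation | coefficients |
|---|---|---|
| linear | $y = ax + b$ | 2 |
| polynomial2 | $y = ax^2 + bx + c$ | 3 |
| power | $y = a x^{b}$ | 2 |
| logarithmic | $y = a + b \ln x$ | 2 |
| exponential10 | $y = a \cdot 10^{bx}$ | 2 |

The exponential family is base-10, exactly as the published per-species
equations are printed; the power family is the classical allometric form.
Linear, quadratic and logarithmic fits are closed-form ordinary least
squares. Power and exponential fits are genuinely nonlinear choices: fitting
them on the log scale minimizes *relative* error and gives coefficients that
are not comparable with the OLS families under an original-scale $R^2$. We
therefore fit them by Levenberg-Marquardt nonlinear least squares on the
original gram scale (`minpack.lm::nlsLM`), initialized from the log-linear
transform fit. `nlsLM` rather than `stats::nls` because the latter cannot
converge on exactly-fitting (zero-residual) data, which our round-trip
verification deliberately uses. Both log-scale and original-scale solutions
are available to the curious via the initialization, but the original-scale
fit is authoritative.

$R^2 = 1 - SS_{res}/SS_{tot}$ is always computed on the untransformed gram
scale about the mean weight, for every family, which is the only way the
five values are mutually comparable. Selection takes the family with the
highest $R^2$; ties are declared at 4-decimal resolution (the precision at
which such values are conventionally reported) and resolved toward the
family with fewest coefficients, then the conventional family order. This
generalizes the published handling of the sandfish data, where the linear
and quadratic equations tie at $R^2 = 0.9882$ and both are reported: exactly
linear data should select the linear family even though the quadratic
reproduces it perfectly.

The fifteen published equations (three species x five families) ship as
fixtures via `load_packaged_models()`; the underlying 60-point datasets are
not public, so these models are carried verbatim, not refitted.

## Marker dictionary, detection, and its accuracy budget

No fiducial-marker library exists in this package's dependency universe, so
marker rendering and detection are implemented here and share one
dictionary: an $(n+2)\times(n+2)$ module grid (a one-module black border
around an $n \times n$ payload) whose payload bits are generated
deterministically from the dictionary name and marker id with a Park-Miller
generator, regenerating until the pattern is rotationally asymmetric and
mixed. This keeps render and detect self-consistent - the property the
pipeline actually relies on - but the bit patterns are **not**
byte-compatible with OpenCV's ArUco dictionaries; `"6x6_250"` here names the
geometry (6x6 payload), not OpenCV's exact code book.

Detection proceeds: Otsu-binarize, label dark connected components, take
each component whose external contour is explained (>= 85% by area) by its
maximum-area quadrilateral, refine the quad corners by total-least-squares
line fits to the contour points of each side (points within 1.5 px of the
side, excluding 4 px around the corners), sample the module grid through
the exact four-point homography (9 sub-samples per module), require an
all-black border, and match the payload against the dictionary under all
four right-angle rotations. The matching rotation both identifies the
marker and fixes the corner order (canonical top-left first, clockwise).
Markers with other ids are ignored silently; zero or multiple matches of
the expected id are hard errors, since either leaves the image without an
unambiguous scale.

The scale uses the arithmetic mean of the four side lengths - not the
square root of the quad's area - because the printed side length is the
defined quantity and the mean is first-order robust to mild perspective
skew. Skew (max/min side ratio above 1.2 by default) is warned about, never
corrected: the protocol is top-view imaging and a rectified scale would
silently hide a violated assumption. On synthetic scenes the recovered
scale is within 0.1% of truth and corners within ~0.5 px; the acceptance
bands (1% scale, 1 px corners) leave room for noise and lighting gradients.

## Segmentation choices

* **Background removal.** The published workflow used a neural matting tool;
  that is a pluggable backend contract here, and the bundled backend is a
  global intensity cut at the image's Otsu threshold (background painted
  white, foreground untouched). It is exact on high-contrast scenes and
  keeps the test suite self-contained; a matting adapter can be dropped in
  behind the same contract.
* **Otsu's threshold** is computed by maximizing between-class variance
  over the 256-bin histogram with cumulative sums; ties break toward the
  lowest threshold. A brute-force search over all 256 candidates is kept in
  the test suite as an oracle. Constant images are an error - no threshold
  exists.
* **Contours.** Each labelled component's external boundary is extracted as
  the 0.5-level marching-squares iso-contour (holes ignored), which runs
  along the half-pixel region boundary. The shoelace area of this polygon
  tracks the raster pixel count to within small corner-cut terms (bounded by
  one perimeter), avoiding the systematic half-perimeter underestimate of a
  pixel-centre contour. Contour shoelace area is the primary measurement;
  raster counting remains the independent oracle in tests.
* **The marker is dark** and would otherwise be measured as an object, so
  its quadrilateral, dilated by a 3 px margin (to swallow anti-aliased or
  noisy edge pixels), is cleared from the mask before measurement.
* **Area filter.** Objects below 5 cm$^2$ (default) are discarded; the
  boundary is inclusive. Width and height are axis-aligned bounding-box
  dimensions in cm. One organism per image is assumed, as in the imaging
  protocol; when several objects pass the filter the largest is used and
  the rest are logged.

## Validation statistics

The error measure is absolute percent error with the hand-weighed value as
denominator, $100\,|{\hat y - y}|/y$ - the published error rates name no
formula, and this is the standard choice that treats over- and
under-estimation symmetrically. The two-sample comparison checks normality
(Shapiro-Wilk, delegated to `stats::shapiro.test`) and variance homogeneity
(Levene's test, mean-centred, implemented from its ANOVA-on-deviations
formula) before the *t* test. The *t* statistic is implemented from first
principles in both forms; Levene's outcome selects between them: pooled
variance when Levene's $p \ge \alpha$, Welch otherwise - the source
protocol checks homogeneity without saying what happens on failure, and
switching to Welch is the choice that keeps the test's size correct either
way. The test is two-sided at $\alpha = 0.05$. Over 10,000 null replicates
the rejection rate is within 0.05 +/- 0.01 (verified in the acceptance
suite).

## What the synthetic scenes do and do not emulate

A scene is: a uniform background (default intensity 170), one dark organism
(default 60), one marker (black 20 / white 245) with 10 cm side, an optional
linear horizontal illumination ramp, additive Gaussian pixel noise (default
sigma 2), and 8-bit quantization. Organisms are disks, ellipses, or
superformula polygons; the polygon variant carries its own shoelace ground
truth so no ground-truth number ever depends on the renderer.
Rasterization is centre-sampling without anti-aliasing, making the
ground-truth pixel count exact and leaving only the perimeter-bounded
discretization error. The batch generator draws scales from 15-40 px/cm and
organism sizes giving roughly 20-140 cm$^2$, matching the size range of the
cultured animals.

Deliberately not modelled: water-column turbidity, refraction, caustics,
shadows, specular glints, texture within the animal, and anything that would
defeat a global threshold. Passing the synthetic suite therefore
demonstrates the geometry, calibration, measurement and statistics are
correct - not that segmentation is robust to difficult underwater optics;
on real imagery the pluggable matting backend and the marker's noise margins
carry that load.

The rotation augmentation (`augment_rotations()`) produces, for each input,
all four right-angle orientations in deterministic order. The source
protocol describes rotating "90 degrees clockwise" yet reports 15
individuals becoming 60 images per species; only the four-orientation
reading is consistent with the count, so that is the implemented semantics.
Right-angle rotations permute pixels exactly, so pixel areas - and
therefore measured physical areas up to re-detection of the marker - are
invariant across the four copies, which the acceptance suite checks at
0.5%.

## Numerical and reproducibility notes

* Rendering is deterministic: identical specs (including seed) give
  bit-identical images; the generator saves and restores the caller's RNG
  state.
* Pipeline runs write `measurements.csv`, `model.json`, `report.json` and a
  manifest (config, seed, skip accounting) and are byte-identical across
  reruns of the same configuration.
* Coefficients are stored at full double precision and rounded to 4
  decimals only for display.
* Negative weight predictions (possible for the quadratic family far
  outside its fitted range) are returned as-is with a notice rather than
  clamped - a silent floor would bias validation statistics.
* Test problem sizes: 50 random scenes for the area-recovery property, 200
  replicates for noise-robustness of the five families, 10,000 replicates
  for type-I calibration. The full suite runs in well under a minute on a
  single CPU.

## Known limitations

* One marker, one organism per image; no multi-marker bundles, no camera
  intrinsics or lens-distortion correction.
* The bundled background backend assumes dark-on-light contrast.
* The packaged species equations apply to the area ranges they were fitted
  on; extrapolation, especially of the quadratic family, is unreliable.
* The validation protocol is the published in-sample "self-test"; an
  independent holdout is supported but the packaged equations cannot be
  re-derived without the original data.
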