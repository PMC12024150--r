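# holoweigh

Non-invasive weight estimation of sea cucumbers (and similar benthic
animals) from single top-view photographs.

Sea cucumbers contract and lose water when handled, so hand-weighing is both
stressful for the animal and biased. `holoweigh` instead estimates weight
from an image: a printed square fiducial marker of known physical side
length (default 10 cm), placed next to the animal, fixes the
pixels-per-centimetre scale of the photograph; the animal is segmented by
Otsu thresholding and contour extraction; its projected dorsal area *x*
(cm²) is converted to weight *y* (g) through a species-specific allometric
regression. It is aimed at aquaculture and marine-ecology workflows where
repeated growth measurements must not disturb the animals.

## The model

The pixels-per-centimetre scale of each image comes from the marker's four
detected side lengths ℓ₁..ℓ₄ and printed side *s*:

    px/cm = mean(ℓ₁..ℓ₄) / s,    area_cm² = pixel_area / (px/cm)²

Area relates to weight through one of five candidate families,

    linear         y = a·x + b
    polynomial2    y = a·x² + b·x + c
    power          y = a·x^b
    logarithmic    y = a + b·ln(x)
    exponential10  y = a·10^(b·x)

fitted by (nonlinear) least squares on the original gram scale and ranked
by the coefficient of determination R² = 1 − SS_res/SS_tot; ties at
4-decimal resolution go to the family with fewest coefficients. Published
equations for three Thai species — black sea cucumber (*Holothuria
leucospilota*), pink warty sea cucumber (*Cercodemas anceps*) and sandfish
(*Holothuria scabra*) — ship as ready-to-use models
(`load_packaged_models()`). Estimates are validated against hand-weighed
values by absolute percent error and an independent two-sample *t* test
guarded by Shapiro–Wilk and Levene checks.

A synthetic-scene generator with exact ground truth (marker corners, true
scale, true organism area) makes the whole pipeline testable without any
photograph; see the methods vignette (`vignettes/holoweigh-methods.Rmd`)
for the design rationale and accuracy budgets.

## Worked example

```r
library(holoweigh)

## a synthetic scene: 7 x 3 cm ellipse + 10 cm marker at a true 22 px/cm
spec <- scene_spec(pixels_per_cm = 22,
                   organism = list(shape = "ellipse", semi_a_cm = 7,
                                   semi_b_cm = 3, angle_deg = 25),
                   seed = 42)
scene <- render_scene(spec)

obs <- detect_marker(scene$image)
cal <- compute_scale(obs, marker_side_cm = 10)
cal
#> scale calibration: 22.100 px/cm (marker id 1, side 10.0 cm, skew 1.000)

mask <- mask_marker_region(binarize(scene$image), obs)
objects <- measure_objects(mask, cal, min_area_cm2 = 5)
objects[[1]]
#> segmented object: area 65.38 cm2, bbox 12.9 x 8.0 cm, 31935 px
scene$truth$analytic_area_cm2
#> [1] 65.97345

model <- load_packaged_models("sandfish")$linear
model
#> linear model [sandfish]: y = 2.2761x -10.3947  (R2 = 0.9882, n = 60)
predict_weight(model, objects[[1]]$area_cm2)
#> [1] 138.4272
```

The calibration recovers the true 22 px/cm to 0.5%; the measured area is
within 1% of the analytic ellipse area π·7·3 ≈ 65.97 cm²; the packaged
sandfish equation then converts the area to an estimated weight of 138 g.

For batch work there is a thin command line (`exec/holoweigh`) with
subcommands `generate`, `measure`, `fit`, `predict`, `validate` and `run`
(end-to-end: images + weights CSV → measurements, selected model,
validation report, manifest).

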