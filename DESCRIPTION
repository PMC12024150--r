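Package: holoweigh
Title: Non-Invasive Weight Estimation of Sea Cucumbers from Top-View
    Images with Fiducial-Marker Scale Calibration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the body weight of cultured sea cucumbers from single
    top-view photographs without handling the animals. A printed square
    fiducial marker of known physical side length placed next to the animal
    provides the pixels-per-centimetre scale; the animal is segmented by
    Otsu thresholding and contour extraction, its projected dorsal area is
    converted to square centimetres, and species-specific area-weight
    regression models (linear, quadratic, power, logarithmic and base-10
    exponential families, selected by coefficient of determination) convert
    area to weight in grams. Includes a validation protocol (percent error,
    Shapiro-Wilk, Levene and two-sample t tests), packaged regression
    equations for three Thai sea cucumber species, and a synthetic-scene
    generator with exact ground truth so the whole pipeline is testable
    without photographs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    minpack.lm,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    car,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
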