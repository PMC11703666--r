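Package: dreamaffect
Title: Activation-Maximized Visual Stimuli and Affective Rating Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying human emotional reactions to images synthesized
    by activation maximization ("deep dreaming") of convolutional network
    layers. Provides a model-agnostic gradient-ascent synthesis engine with a
    packaged 144-name Inception-style layer inventory, six global image
    properties (mean hue, saturation and brightness in the 8-bit HSV dialect,
    JPEG compression percentage, and the Feature Congestion and Sub-band
    Entropy visual-clutter measures), a simulator of the arousal/valence
    slider-rating protocol with residual noise calibratable to a target
    population R-squared, and the layer-level statistical analyses: Pearson
    correlations, six-predictor multiple regression, one-way ANOVA, per-layer
    neutrality and layer-family comparisons, smoothed joint arousal-valence
    densities ranked by Shannon entropy, and anchor-nearest layer search.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    jpeg,
    jsonlite,
    MASS,
    png,
    stats,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
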