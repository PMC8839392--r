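Package: rgbdgait
Title: Markerless Gait Analysis from a Single RGB-D Camera
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates spatio-temporal gait parameters and center-of-mass sway
    from 25-joint skeletal trajectories captured by a single RGB-D (depth)
    camera while a subject walks toward the sensor along a reduced walking
    path. Provides the full processing chain (cubic resampling to a uniform
    50 Hz grid, zero-phase 10 Hz low-pass filtering, detection of the gait
    analysis path window from the body center of mass, step segmentation by
    2 cm binary thresholding of the ankle depth trajectories) together with a
    ground-truth-annotated synthetic gait generator, a method-agreement
    statistics layer (Wilcoxon, Spearman, ICC(2,1), Bland-Altman, mixed
    repeated-measures ANOVA) and plotting utilities for gait-pattern maps,
    radar profiles and Bland-Altman panels.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    jsonlite,
    nortest,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
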