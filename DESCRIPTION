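Package: lpmatch
Title: Log-Polar Magnitude Feature Descriptor and Image Matching
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Rotation-, scale- and illumination-invariant local feature
    description for grayscale raster images (microscopy and natural
    scenes) based on log-polar resampling of circular feature
    neighbourhoods followed by selection of Fourier magnitude-spectrum
    components. Includes Harris corner and determinant-of-Hessian blob
    detectors, an adapter for externally detected features, exhaustive
    thresholded matching with the Lowe ratio test, RANSAC homography
    verification, overlap-error based evaluation metrics, an optional
    scale pyramid for large zoom differences, a seeded synthetic image
    generator with ground-truth homographies, and a command-line
    interface chaining all stages.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    png,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
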