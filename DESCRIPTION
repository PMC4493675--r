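Package: hoofstride
Title: Footfall Event Detection and Stride Segmentation from a Single Hoof Marker
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Detects foot-on and foot-off events in hoofed gait from the 3D
    trajectory of a single marker on the dorsal hoof wall. Implements four
    kinematic detection algorithms (resultant-velocity thresholding,
    trigonometric breakover distance, filtered-acceleration peaks and
    vertical-velocity minima), force-plate reference event detection with a
    configurable vertical-force threshold, descriptive method-comparison
    statistics (limits of agreement, accuracy, between- and within-subject
    precision), and a seeded synthetic gait generator with known ground-truth
    events for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    stats,
    utils,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
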