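Package: ommatidia
Title: Automated Morphometry of Arthropod Compound Eyes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Detects and measures ommatidia, the repeated optical units of
    arthropod compound eyes. A reciprocal-space (2D FFT) detector locates the
    hexagonal facet lattice in micrographs and returns lens centers, counts
    and per-facet diameters; a volumetric pipeline segments crystalline-cone
    clusters in micro-CT stacks and derives lens diameter, ommatidial axis
    skewness, anatomical interommatidial angles and field of view. Includes
    closed-form optical geometry (interommatidial angle, radius of curvature,
    oval-eye lattice analysis, world-referenced projection), synthetic eye
    generators for validation, and a resolution/contrast degradation
    benchmark.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tiff,
    png,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
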