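Package: betulaSize
Title: Automated Size Measurement and Species Unmixing of Birch Pollen
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Measures the calibrated area and rotational mean width of birch
    (Betula) pollen grains from binary outlines, screens grains for
    measurement suitability, applies z-score outlier filtering and
    stratigraphic pooling to per-sample size series, and estimates the
    proportion of pollen from up to four birch species by fitting a compound
    (mixture of normals) size distribution with differential evolution over
    the proportion simplex. Includes a classical fallback segmenter for
    microscope images, best-focus layer selection for image stacks, a
    synthetic scene and mixture generator with analytic ground truth, and a
    packaged reference table of species size parameters for silicone-oil
    mounted material.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    tiff,
    png,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
biocViews: Software, CellBiology, Classification, Visualization
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
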