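Package: zoneQuant
Title: Quantification of Exclusion-Zone Cell Migration Assays
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying insert-based (exclusion-zone) cell
    migration assays from brightfield time-lapse images. Implements the
    full image-analysis chain (8-bit grayscale conversion, Sobel edge
    enhancement, maximum-entropy thresholding, binary morphology and
    calibrated particle analysis of the cell-free area), migration
    kinetics with the associated statistical comparisons, a simplified
    centroid tracker for cell-velocity estimation, and a synthetic-assay
    simulator producing time-lapse well images with known ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tiff,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    ggplot2,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: CellBiology, Visualization, Software
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'insert-geometry.R'
    'io.R'
    'kinetics.R'
    'segmentation.R'
    'synthetic-assay.R'
    'tracking.R'
    'zoneQuant-package.R'
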