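Package: nervenano
Title: Morphometry of Myelinated Nerve Fibres in X-Ray Holographic Nanotomography Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for analysing 3D X-ray phase-contrast holographic
    nanotomography volumes of peripheral nerve tissue. Provides semi-automated
    segmentation of individual myelinated fibres by slice-propagated closed
    curves (polar dynamic programming attracted to the dark myelin boundary),
    morphometry of healthy and regenerating fibres (equivalent diameters,
    myelin thickness, g-ratio, fibre density, node-of-Ranvier gap detection,
    and a winding-number intertwining statistic for regenerative clusters),
    spatial-resolution estimation by hyperbolic-tangent edge-spread fitting,
    and a synthetic phantom generator with full geometric and voxel-level
    ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    tiff,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
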