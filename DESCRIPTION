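Package: footprintr
Title: Ligament Insertion Footprint Morphometry from 3D Label Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies ligament insertion footprints from multi-label 3D
    segmentation volumes of the distal radioulnar joint. Implements the
    extraction chain (label smoothing, Sobel boundary delineation,
    dilation-erosion overlap detection, maximum-component selection and
    RANSAC plane refinement), planar morphometry (area, dorsal-volar and
    radial-ulnar maximal lengths, centre thickness, three-way shape
    classification), segmentation overlap metrics (Dice, Soft IoU), and the
    accompanying agreement statistics (two-way random-effects ICC with
    Koo-Li bands, multiple linear regression diagnostics, Cohen's f-squared
    and noncentral-F post hoc power). Ships a seeded synthetic wrist-phantom
    generator with analytically known footprint ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    car,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    oro.nifti,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
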