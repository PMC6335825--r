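Package: phagostate
Title: Quantification of Phagocytic State from Dual-Channel Cell Images
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the phagocytic state of myeloid cells from
    dual-channel fluorescence images (membrane marker plus lysosome or
    bead channel). Implements gray-level co-occurrence matrix (GLCM)
    texture statistics (angular second moment, inverse difference
    moment, entropy) within a traced cell outline, inward Euclidean
    distance shells at fixed nanometre edges with per-shell integrated
    density fractions, shape descriptors (circularity, solidity), bead
    segmentation and counting for time-lapse uptake assays, and a
    ground-truthed synthetic dual-channel cell image generator for
    validating every stage without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    mgcv,
    tiff,
    yaml,
    emmeans
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: CellBiology, Visualization, Software
RoxygenNote: 7.3.3
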