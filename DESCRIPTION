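Package: segLink3D
Title: Forward Coarse-to-Fine 3D Linking of Serial-Section Segmentations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Groups per-slice 2D segmentation masks from serial-section
    electron microscopy into 3D objects using a fast forward coarse-to-fine
    connection algorithm: bounding-box IoU screening, a position/shape
    similarity with a scaling-and-translation transformation search,
    category-driven forward labeling that resolves splits and merges, and a
    skip connection that bridges single missing slices. Includes a 3D
    connected-component baseline, split/merge error metrics against a ground
    truth grouping, and a synthetic stack generator with known 3D labels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    Matrix,
    EBImage,
    tiff,
    png,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
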