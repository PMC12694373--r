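Package: msfdet
Title: Multi-Scale Fusion Components for Imbalanced Leaf-Disease Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Building blocks for real-time detection of plant leaf
    diseases under class imbalance: an adaptive focal loss with a
    dynamic, exponentially smoothed IoU threshold; multi-scale
    dilation residual blocks with lossless reparameterization of
    parallel dilated kernels into a single convolution; a multi-scale
    feature pyramid neck built from depthwise multi-kernel focusing
    modules and a context diffusion stage; random-grouping
    undersampling for constructing imbalanced detection datasets with
    share and ratio statistics; a seeded synthetic leaf-lesion scene
    generator with bounding-box annotations in COCO JSON and YOLO
    text formats, standard augmentations and a salt-noise robustness
    protocol; and COCO-style average-precision evaluation. All
    numerics run on plain R arrays so every component is testable on
    a desktop CPU without GPU frameworks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
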