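Package: germseg
Title: 3D Instance Segmentation of C. elegans Germline Nuclei in Fluorescence Z-Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for segmenting densely packed nuclei of the
    C. elegans distal germline in anisotropic 3D fluorescence z-stacks.
    Provides physical-units preprocessing (rescaling to a 30-pixel nucleus
    diameter, anisotropy computation, Gaussian blurring), a pluggable 3D
    instance-segmentation backend contract with a classical
    blob-detection/watershed baseline and an adapter stub for a retrained
    Cellpose model, border and shape post-filtering of label volumes,
    instance-matched Jaccard-index evaluation, orthogonal-view ground-truth
    preparation with reproducible augmentation, and a ground-truthed synthetic
    germline scene generator so every stage is testable without microscopy
    data or trained network weights.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    tiff,
    yaml,
    Rcpp,
    stats,
    grDevices,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage,
    jsonlite,
    optparse
Config/testthat/edition: 3
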