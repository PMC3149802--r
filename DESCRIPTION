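Package: spineasm
Title: Active Shape Model Segmentation of Vertebrae in Radiograph-Like Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains point-distribution models of vertebral bodies from
    landmarked training images (generalized Procrustes alignment followed by
    principal-component analysis of the aligned landmark coordinates), learns
    grey-level gradient profile statistics along landmark normals, and segments
    vertebrae in new grey-level images with the iterative Active Shape Model
    search. Initialization is semiautomatic: from two user-supplied anchor
    points the anterior corners of the N vertebrae are located with a Harris
    corner detector, Canny-edge-based candidate filters, and a recursive
    shortest-path search constrained by a geometric spine prior. Includes a
    seeded synthetic spine-image generator for training and validation without
    external data, and point-to-line / point-to-point evaluation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    png,
    tiff,
    EBImage,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
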