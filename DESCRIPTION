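Package: maaseg
Title: Weakly Supervised Gland Segmentation with Multi-Level Attention and
    Pixel Affinity Refinement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-stage weakly supervised semantic segmentation of glands in
    H&E histology images from image-level labels alone. Stage one trains a
    small hierarchical transformer encoder whose multi-level features
    (layers 3, 5 and 6) are fused into class activation maps; the maps are
    turned into confidence pseudo-labels, refined by pixel-adaptive
    smoothing and a learned-affinity random walk. Stage two trains a
    pyramid-pooling segmentation network on the refined pseudo-labels with
    an online easy-example-mining loss that down-weights noisy pixels.
    Includes a deterministic synthetic H&E tile generator, sliding-window
    tiling and stitching utilities, IoU/Dice evaluation, and a YAML-driven
    pipeline runner, all exercisable at desk scale on one CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    png,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
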