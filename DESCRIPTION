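Package: nucseg
Title: Dense Nuclei Instance Segmentation with Multi-Path Dilated Residual Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for instance segmentation of dense, small cell nuclei in
    microscopy images. Provides a multi-path dilated residual backbone with
    receptive-field and pixel-coverage diagnostics, feature-pyramid fusion with
    an equal-resolution (no-upsample) top-down rule, region-proposal machinery
    (anchors, box parameterization, smooth-L1/RPN losses, non-maximum
    suppression), detection heads (ROI-align pooling, softmax classification,
    box regression, mask prediction), selectable group/batch normalization,
    a replayable stochastic augmentation protocol for paired image/annotation
    data, object- and pixel-level evaluation metrics (F1, Jaccard, aggregated
    Jaccard index), and a seeded synthetic dense-nuclei scene generator so the
    full train/predict/evaluate pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    png,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr,
    yaml
Config/testthat/edition: 3
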