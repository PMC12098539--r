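Package: semiseg
Title: Semi-Supervised Tumor Segmentation for H&E Histopathology Tiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A mean-teacher semi-supervised training library for binary tumor
    segmentation of hematoxylin-and-eosin (H&E) stained pathology tiles. Implements
    a boundary-aware enhanced U-Net (Sobel boundary branch with channel-attention
    fusion), transformation-based uncertainty masking (Monte-Carlo dropout entropy
    combined with a seven-transform agreement mask), multi-scale class-prototype
    contrastive learning with an InfoNCE-style loss, a Gaussian ramp-up weighting
    schedule, and the standard segmentation metrics (overall/average accuracy,
    Dice, Jaccard, 95th-percentile Hausdorff distance). Ships a seedable synthetic
    H&E tile generator so the whole pipeline is testable on CPU without any
    external dataset, and a compact tape-based reverse-mode autodiff core so no
    deep-learning framework is required.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
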