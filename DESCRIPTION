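Package: greenprompt
Title: Vegetation-Cover-Aware Prompt Generation for Zero-Shot Plant
    Instance Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates high-quality box and point prompts for promptable
    segmentation models applied to plant imagery from vertical farms.
    Implements Vegetation-Cover-Aware Non-Maximum Suppression (VC-NMS),
    which fuses a Normalized Cover Green Index (derived from the Excess
    Green vegetation index and Otsu thresholding) with detector confidence
    and suppresses redundant or multi-plant union boxes via overlap-count
    attenuation and a Relative-IoU Gaussian decay. Also provides
    similarity-map point-prompt augmentation with a max-distance
    criterion, greedy and Soft-NMS baselines, a detection and
    segmentation evaluation suite (COCO-style AP, Dice, expected
    calibration error, S-measure, weighted F-measure), and a seeded
    synthetic vertical-farm scene generator with deterministic mock
    detector, embedder and segmenter backends so the whole pipeline is
    testable without pretrained weights.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
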