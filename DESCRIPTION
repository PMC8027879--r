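Package: meibomorph
Title: Meibomian Gland Segmentation and Morphometry for Infrared Meibography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Automatic analysis of infrared meibography images of the everted
    eyelid. Provides a trainable encoder-decoder (U-Net style) segmentation
    network optimized with a combined cross-entropy and Dice objective, a
    morphometry engine that derives gland number, length, width and
    tortuosity from binary gland masks via skeletonization, the associated
    evaluation statistics (pixel-wise precision/recall/F1, Dice, ROC AUC,
    Bland-Altman agreement, Cohen's kappa, intraclass correlation), and a
    synthetic phantom generator that produces eyelid-like images with exact
    ground-truth masks and analytically known morphometry for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    igraph,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
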