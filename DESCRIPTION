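Package: akuseg
Title: Semantic Segmentation of Actinic Keratosis in Wide-Field Clinical Photography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection of actinic-keratosis-affected skin in wide-field
    clinical photographs by binary semantic segmentation. Implements a
    U-Net style encoder-decoder with convolutional-LSTM fusion of the
    skip connections, a batch-normalized decoder and a sigmoid pixel
    head, trained with pixel-averaged binary cross-entropy; a
    lesion-box patch-extraction pipeline with translation augmentation
    and patient-level splitting; pad-tile-aggregate inference for
    photographs larger than the network input; pixel-overlap (Dice,
    IoU) and region-tolerant (aRec, aPrec, aF1) evaluation metrics;
    and a seeded generator of synthetic skin scenes with exact ground
    truth so the whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
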