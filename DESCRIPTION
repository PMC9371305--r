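Package: tfnnmil
Title: Tensor-Factorized Neural Networks for Multiple-Instance Speech Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Speaker-level binary classification from bags of speech
    utterances using Tucker-style tensor-factorized neural network (TFNN)
    layers under a multiple-instance learning (MIL) protocol. Provides
    order-3 tensor algebra (unfolding, mode products, multilinear
    transforms), learnable 2D/3D tensor feed-forward layers with
    utterance attention and statistics pooling, a convolutional MIL
    baseline, a log-mel spectrogram audio front-end with energy-based
    utterance segmentation, bag formation with ROC-based threshold
    selection, a class-weighted training loop with full analytic
    gradients, and a seeded synthetic corpus generator with controllable
    MIL structure for end-to-end validation without restricted clinical
    audio.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
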