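Package: bruitnet
Title: Classification of Arteriovenous Fistula Shunt Sounds with a
    Convolutional-Attention Recurrent Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for classifying arteriovenous fistula (AVF) bruit
    recordings as normal or abnormal (stenotic). Provides a seeded
    synthetic bruit generator, waveform augmentation (additive white
    noise, random clipping) with stratified dataset splitting, a fused
    Mel-spectrogram and MFCC feature front end with two-stage min-max
    normalization, a convolutional network with channel and spatial
    attention (CBAM) followed by an LSTM sequence classifier trained by
    backpropagation with Adam, and an evaluation suite (confusion
    matrix, precision/recall/F1/accuracy, AUROC, and PSNR/SSIM
    spectrogram comparison). All stages are deterministic given seeds
    and composable into a single reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
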