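Package: esdm
Title: Multi-Task Segmentation and Denoising of Oral OCT B-Frames
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simultaneous speckle denoising and epithelium/stroma segmentation
    of single-repetition oral optical coherence tomography (OCT) B-frames with
    an efficient multi-task encoder-decoder network (ESDM). The shared encoder
    combines strided convolutions with separable convolutional transformer
    blocks; a deconvolution decoder with squeeze-and-excitation gated skip
    connections reconstructs the denoised image while a lightweight linear
    decoder predicts the layer mask. The package also provides the full
    surrounding pipeline: a layered speckle phantom generator, frame-averaging
    ground-truth construction, pseudo-label semi-supervision with soft-label
    encoding, the combined MSE/content/cross-entropy objective, CPU training
    and inference, image-quality (PSNR, SSIM) and segmentation (mDice, mIoU)
    metrics, model complexity reporting, and epithelium thickness
    quantification with refractive-index correction.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    tiff,
    png,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
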