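Package: tumorseg
Title: Attention-Gated Ensemble Segmentation of Brain Tumor Slices with
    Autoencoder Latent ROI Generation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-phase pipeline for binary tumor segmentation of 2D
    brain-MRI slices: (1) a convolutional autoencoder with scaled dot-product
    self-attention at the bottleneck, pre-trained by reconstruction; (2) a
    residual CNN tumor-presence classifier with softmax gating plus k-means
    clustering of the latent feature map to propose a coarse region of
    interest; (3) an ensemble of an attention-gated U-Net and a
    residual-encoder U-Net trained with a hybrid Dice + binary cross-entropy
    loss and fused by soft voting.  Includes a subject-structured synthetic
    phantom generator, stratified subject-wise splitting, joint image/mask
    augmentation, and a full metric suite (Dice, Jaccard, sensitivity,
    specificity, AUC-ROC, 95th-percentile Hausdorff distance).  All data
    generation and training are deterministic given a seed; the
    neural-network core (convolution, batch normalisation, attention, Adam)
    is implemented in vectorised base R.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
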