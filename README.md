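# tumorseg

Attention-gated ensemble segmentation of brain-tumor MRI slices, with
autoencoder representation learning, classifier gating, and latent-space
k-means region proposals — fully testable on a CPU through a built-in
synthetic phantom generator.

## What it does, and for whom

Delineating tumors in brain MRI is slow, expert work; automated binary
segmentation (tumor vs background, one mask per 2D slice) supports
radiologists and downstream volumetry.  `tumorseg` implements a
three-phase pipeline for this task and is aimed at methods researchers and
students who want a *complete, deterministic, inspectable* reference
implementation — every layer of the networks (convolutions, batch norm,
attention, Adam) is written in vectorised base R, and every stage is
exercised end-to-end on synthetic phantoms in minutes:

1. **Representation learning** — a convolutional autoencoder with scaled
   dot-product self-attention at the bottleneck,
   `Attention(Q,K,V) = softmax(QKᵀ/√d_k)V`, pre-trained by reconstruction
   (`build_gae()`, `pretrain_gae()`, `encode_image()`).
2. **Detection + coarse localisation** — a residual CNN classifier with
   softmax probabilities `P(Yᵢ) = exp(xᵢ)/Σⱼexp(xⱼ)` gates segmentation to
   tumor-positive slices; k-means on the latent feature map proposes a
   coarse ROI (`build_classifier()`, `classify()`, `gate()`,
   `kmeans_latent()`, `roi_from_clusters()`).
3. **Ensemble segmentation** — an attention-gated U-Net and a
   residual-encoder U-Net trained with the hybrid loss
   `L = α·L_BCE + (1−α)·L_Dice`, where
   `L_Dice = 1 − (2Σyŷ + ε)/(Σy + Σŷ + ε)`, fused by soft voting
   (`build_attention_unet()`, `build_residual_unet()`,
   `train_segmenter()`, `soft_vote()`, `predict_mask()`).

Evaluation covers Dice, Jaccard, sensitivity, specificity, AUC-ROC and the
95th-percentile Hausdorff distance (`evaluate_dataset()`, `hd95()`), and
preprocessing provides z-score normalization, bilinear/nearest resizing,
joint image/mask augmentation, and stratified *subject-wise* splitting
with a fixed seed so no patient's slices straddle two splits.

## Worked example

```r
library(tumorseg)

## synthetic phantoms: 10 subjects x 3 slices, half tumor-positive
spec <- phantom_spec(image_size = 64, n_subjects = 10, slices_per_subject = 3,
                     tumor_prevalence = 0.5, seed = 42)
ds <- generate_dataset(spec)
s <- ds$samples[[1]]
cat("label:", s$label, " tumor pixels:", sum(s$mask), "\n")
#> label: tumor  tumor pixels: 426

## overlap metrics on a hand-checkable pair: |X| = |Y| = 4, overlap 2
x <- matrix(0, 4, 4); x[1:2, 1:2] <- 1
y <- matrix(0, 4, 4); y[2:3, 1:2] <- 1
dice_coefficient(x, y)   # 2*2/(4+4)
#> [1] 0.5
jaccard_index(x, y)      # 2/6
#> [1] 0.3333333

## boundary error: two single-pixel masks five columns apart
a <- matrix(0, 10, 10); a[5, 2] <- 1
b <- matrix(0, 10, 10); b[5, 7] <- 1
hd95(a, b)
#> [1] 5

## the bottleneck attention operator, hand-checkable at d_k = 1
scaled_dot_attention(Q = matrix(c(1, 0), 1, 2), K = diag(2), V = diag(2),
                     d_k = 1)$output        # softmax(1, 0) = (0.731, 0.269)
#>        [,1]   [,2]
#> [1,] 0.7311 0.2689
```

Running the whole pipeline (phantom generation → subject-wise split →
autoencoder pre-training → classifier → latent k-means ROIs → U-Net
ensemble → gated prediction → metrics) takes ≈ 8–10 minutes on one CPU
core at the default desk scale (300 slices, 64×64):

```r
report <- run_pipeline(pipeline_config(global_seed = 42))
print(report)
#> Pipeline run (seed 42)
#>   components: use_gae_pretrain, use_attention, use_kmeans_roi, use_gate, use_ensemble
#>   ...
#> Segmentation metrics over 80 samples
#>   Dice        0.9834
#>   Jaccard     0.9681
#>   ...
#> Classification: accuracy 1.0000, AUC-ROC 1.0000
```

Dice/Jaccard are macro-averaged over held-out test slices (negatives
count 1.0 when correctly left empty); classification accuracy is the gate
decision vs the slice label.  `ablation_ladder()` runs the five component
configurations (plain U-Net → … → full gated ensemble) on identical data
and tabulates Dice, Jaccard, sensitivity, and HD95 per row.

A thin CLI mirrors these entry points
(`Rscript inst/cli/tumorseg.R run-all --seed 42 --output-dir out/`), with
subcommands `simulate`, `split`, `pretrain-gae`, `train-classifier`,
`train-seg`, `predict`, `evaluate`, `run-all`, `ablation-ladder`.

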