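---
title: "Methods: attention-gated ensemble segmentation with autoencoder latent ROIs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: attention-gated ensemble segmentation with autoencoder latent ROIs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the pipeline

`tumorseg` implements a three-phase pipeline for binary tumor segmentation
of 2D brain-MRI slices, together with a synthetic phantom generator that
makes every stage testable on a laptop CPU without any external dataset.

**Phase 1 — representation learning.** A convolutional autoencoder is
pre-trained to reconstruct the (z-scored) input slice under mean-squared
error.  The encoder is a chain of conv(3×3, stride 2) → batch-norm → ReLU
stages, each halving resolution; at the bottleneck a scaled dot-product
self-attention block acts on the flattened spatial positions,

$$\mathrm{Attention}(Q,K,V) = \mathrm{softmax}\!\left(\frac{QK^\top}{\sqrt{d_k}}\right)V,$$

with learned linear projections for $Q$, $K$, $V$ and a residual
connection.  The decoder mirrors the encoder with nearest-neighbor
upsampling + conv stages and a linear 1×1 head (reconstructions are
real-valued, matching standardized inputs).

**Phase 2 — detection and coarse localisation.** A small residual CNN
classifier (conv stem, residual blocks with stride-2 downsampling, global
average pooling, dense softmax head) predicts tumor presence,
$P(Y_i) = e^{x_i} / \sum_j e^{x_j}$.  Segmentation runs only when the
tumor probability reaches the gate threshold $\tau$ (default 0.5);
otherwise the predicted mask is all-zero.  For segmented cases, k-means
(k = 2 by default) clusters the latent feature vectors of the encoder's
bottleneck grid; the minority cluster with the higher mean activation norm
is taken as the tumor-like region, dilated by one latent cell, and
upsampled to image resolution as a coarse region of interest (ROI).

**Phase 3 — ensemble segmentation.** Two U-Net-family members — an
attention-gated U-Net (additive gates on every skip connection) and a
residual-encoder U-Net with plain skips — are trained with the hybrid loss

$$L = \alpha\, L_{\mathrm{BCE}} + (1-\alpha)\, L_{\mathrm{Dice}},\qquad
L_{\mathrm{Dice}} = 1 - \frac{2\sum_i y_i \hat y_i + \epsilon}
{\sum_i y_i + \sum_i \hat y_i + \epsilon},$$

and fused by soft voting (weighted mean of probability maps, default equal
weights) before thresholding at 0.5.  The attention U-Net's encoder can be
initialised from the pre-trained autoencoder encoder; the residual member
trains from scratch, which keeps the ensemble diverse.

Two *different* attention mechanisms coexist deliberately: transformer
self-attention at the autoencoder bottleneck (long-range context over
positions) and additive sigmoid gates on U-Net skips (per-position feature
suppression).  They are not interchangeable and are implemented as
separate operators (`scaled_dot_attention()`, `attention_gate()`).

## Parameters that matter

| Parameter | Default | Notes |
|---|---|---|
| optimizer / batch size | Adam, 8 | framework-wide setting |
| learning rate | 3e-4 (classifier); 1e-3 (autoencoder, segmenters) | see below |
| $\alpha$ (BCE weight) | 0.5 | balances pixel accuracy vs region overlap; `scripts/alpha_sweep.R` sweeps {0.3, 0.5, 0.7} |
| $\epsilon$ (Dice smoothing) | 1e-6 | must be ≪ typical mask sums; both-empty masks give loss 0 exactly |
| gate threshold $\tau$ | 0.5 | equals the arg-max decision |
| k (latent clusters) | 2 | tumor vs background |
| ROI dilation | 1 latent cell | a coarse proposal must not exclude tumor tissue |
| binarize threshold | 0.5 | on the fused probability map |
| seed | 42 | applied to splitting, initialisation, shuffling, augmentation, k-means |

The framework's reference step size is 3e-4; the desk-scale presets train
the autoencoder for 5 epochs and each segmenter for 8 epochs (≈ 360
gradient steps), far fewer than a GPU-scale schedule, so those two stages
use 1e-3 to reach a useful optimum within their budget.  The classifier
converges comfortably at 3e-4 and keeps it.

He-normal initialisation (sd $=\sqrt{2/\mathrm{fan_{in}}}$) is drawn from
a seeded RNG; rebuilding any model from `(config, init_seed)` reproduces
bit-identical parameters.  Every stochastic component derives its stream
from the global seed through an order-independent integer hash
(`hash_seed()`), so generating sample (i, j) alone or within a full
dataset yields the same bits.

## Preprocessing and splitting

Intensity normalization is the z-score $X_{\mathrm{std}} = (X-\mu)/\sigma$
with the *population* standard deviation (the formula carries no Bessel
correction).  It is applied per image by default; a dataset-level variant
(reusing stored $\mu,\sigma$) is available via the `params` argument.
Resizing uses pixel-center bilinear interpolation for images and
nearest-neighbor for masks (preserving binarity); the coordinate
convention is row-major, 0-based, pixel centers at integer coordinates.
Augmentation draws rotations in ±10°, integer translations in ±5 px, and
horizontal/vertical flips, applying one identical geometric transform to
image (bilinear) and mask (nearest) with constant-zero padding — rotation
about the image center invents no tissue.

Splitting is stratified *and* subject-wise simultaneously: subjects are
shuffled within each class and allocated by largest-remainder rounding to
the (0.622, 0.155, 0.223) fractions, so all slices of a patient land in
one split and each split's class mix is within one subject of the ideal.
Augmentation happens *after* splitting by default; augmenting before
splitting would leak augmented copies of test subjects into training, and
the package only exposes the leakage-free order.

## The phantom generator

Each subject owns an elliptical lesion (semi-axes drawn from
`tumor_radius_range`, random orientation) whose center/orientation/radii
jitter slightly per slice (±2 px, ±10°, ±1%), over a smooth background
field (white noise on a coarse grid, bilinearly upsampled, correlation
length `background_texture_scale` ≈ 8 px) plus i.i.d. Gaussian noise.
Tumor-positive subjects are the first `round(prevalence · n_subjects)`
indices — exact class counts, randomised later by the split shuffle.  The
generator emulates: subject structure, class imbalance, roughly elliptical
bright lesions, textured background, and additive noise.  It does **not**
emulate MRI physics — no bias fields, no T1/T2/FLAIR contrast, no 3D
continuity, no skull or anatomy.  Passing tests therefore demonstrate that
the machinery (architectures, losses, training, gating, clustering,
metrics) is correct and that the pipeline can recover bright compact
lesions; they do not certify performance on clinical MRI.

Default study conditions (the desk scale): 300 slices of 64×64 px from 30
subjects × 10 slices, prevalence 0.5, radii 6–12 px, contrast 0.6 over a
0.35 background with noise σ = 0.05 — a clearly visible but noisy lesion,
about 2–11% of the image area.

## Numerical choices

* **Soft Dice pools all pixels of a batch** as one set, so empty-mask
  slices contribute only to the denominator; with $\epsilon$ = 1e-6 an
  all-empty batch yields loss exactly 0.
* **BCE clips predictions** to $[10^{-7}, 1-10^{-7}]$; the gradient is
  zeroed in the clipped region.
* **HD95** extracts boundary pixels (positive with a non-positive
  4-neighbor, image border counts as outside), takes nearest-neighbor
  Euclidean distances in both directions, and uses linear interpolation
  between order statistics (R's quantile type 7) for the 95th percentile —
  pinned so tests are bit-stable.  Macro (per-sample) averaging is the
  default for segmentation metrics; samples with an empty mask on either
  side are skipped for HD95 and flagged, never silently imputed; an empty
  prediction against a non-empty truth scores Dice 0.
* **AUC-ROC** uses the rank (Mann–Whitney) statistic with midranks, i.e.
  $P(s^+ > s^-) + \tfrac12 P(\text{tie})$.
* **k-means** runs Lloyd's algorithm with k-means++ seeding, 10 restarts
  (best inertia wins, earliest restart on ties), equidistant points to the
  lowest cluster index, and empty clusters re-seeded at the farthest
  point.  Restarts make the tiny-problem optimum (n ≤ 8) coincide with the
  exhaustive-partition minimum in practice.
* **Batch norm** uses population batch statistics in training and running
  averages (momentum 0.1) at evaluation.
* **Early stopping** restores the best-validation parameters after
  `patience` epochs without improvement; requesting it without a
  validation set is an error, not a silent no-op.

## Design decisions on open points

* The architecture text places self-attention "during encoding and
  decoding" in one phase overview but at the bottleneck in the detailed
  description; the package implements bottleneck-only attention (the
  detailed variant) — per-stage gates in the *decoder* exist separately as
  the U-Net attention gates.
* Whether the classifier consumes the image or the latent map is
  ambiguous (a ResNet-family backbone suggests image scale, the phase
  description says latent features feed it); the default is the image,
  with `classifier_config(input = "latent")` wired and tested.
* The ROI's mechanism for "constraining the search space" is unspecified;
  the default concatenates the ROI as an extra input channel
  (`mask_input_channel`), with `restrict_loss` (loss evaluated inside a
  dilated ROI only) as an alternative.
* Clustering "either on the latent feature map or a coarse segmentation
  output": only the latent variant is implemented; the second is
  undefined and was not guessed.
* Ensemble membership is exactly the two named families (attention U-Net,
  residual-encoder U-Net) with equal vote weights; the member list and
  weights are configurable.
* Epochs-vs-iterations: the reference training table lists both 20 epochs
  and 1 000 iterations; epochs are treated as authoritative and the
  iteration count follows from the data size.
* The U-Net encoder topology intentionally matches the autoencoder's
  (stride-2 stages, no full-resolution stem; the full-resolution skip is
  the input itself) so that pre-trained encoder weights transfer
  stage-by-stage.  When the ROI adds an input channel, the first-stage
  kernel transfers into the image-channel slice and the ROI slice keeps
  its fresh initialisation.

## Problem sizes used by the test suite

Unit tests run on 8–32 px inputs with 2–6-channel networks.  The
end-to-end checks use the desk preset (300 × 64×64 slices; autoencoder 5
epochs, classifier ≤ 8, segmenters ≤ 8, batch 8), which completes the full
five-stage pipeline in roughly 8–10 minutes on one CPU core;
determinism-of-complete-runs is exercised at a reduced size (36 × 32×32
slices, 2–3 epochs) because it needs two identical runs.  The ablation
ladder in tests likewise uses the reduced size; `ablation_ladder()` on the
desk preset reproduces the five-configuration table at full desk scale
when run directly.

## Known limitations

* The NN core is vectorised base R; it is fast enough for desk-scale
  experiments and CI, not for 224×224 GPU-scale training.
* Phantoms are far easier than clinical MRI; absolute metric values on
  phantoms (Dice ≈ 0.95+) say nothing about clinical performance.
* Latent k-means assumes the tumor forms a minority, high-activation
  cluster; on negative slices the ROI proposal is spurious by
  construction and only useful downstream because the gate (or the mask
  supervision) suppresses it.
* The both-empty Dice/Jaccard convention (1.0, with a warning at the
  single-pair level) rewards correct negatives; when comparing methods on
  mixed positive/negative test sets the per-sample table in the metrics
  report should be consulted alongside the means.
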