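---
title: "Multi-task denoising and segmentation of oral OCT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-task denoising and segmentation of oral OCT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esdm)
```

## The problem

Optical coherence tomography (OCT) of the oral mucosa suffers from two
coupled problems.  Speckle — the multiplicative interference noise inherent
to coherent imaging — obscures tissue structure in a single B-frame, and the
standard remedy, averaging several repeated acquisitions of the same
location, multiplies the scan time and with it the risk of motion artifacts
in hand-held intraoral scanning.  At the same time the clinically relevant
quantity, the thickness of the epithelium above the stroma, requires a
per-pixel segmentation that is hard even for experts because the two layers
have similar backscatter.

This package implements a single network that addresses both at once: from a
**one-repetition** B-frame it simultaneously reconstructs a low-noise image
(supervised by the frame average of repeated acquisitions) and predicts a
three-class layer mask (background / epithelium / stroma), from which the
epithelium thickness is quantified in micrometres.

## The network

The model (`esdm_model()`, configured by `esdm_config()`) is an
encoder–decoder with *hard parameter sharing*: one shared encoder, two
task-specific decoders.

**Shared encoder.**  Five downsampling stages (total factor 32).  Stages 1–2
are convolution blocks: a 3×3 stride-2 convolution followed by a 3×3
stride-1 convolution, each with layer normalization and GeLU.  Stages 3–5
each begin with a 3×3 stride-2 embedding convolution (plus layer norm) and
then stack *separable convolutional transformer* (SCT) blocks.  An SCT block
is a pre-norm transformer block whose query/key/value sequences are produced
not by linear patch projections but by a 1×1 convolution followed by a 3×3
depth-wise convolution (`sct_qkv_projection()`), so the attention sees
spatially informed tokens; multi-head scaled dot-product attention
(`multi_head_self_attention()`) with the channel dimension split across
heads is followed by a depth-wise feed-forward network (`dw_ffn()`):
pointwise expansion to 4C channels, a 3×3 depth-wise convolution, GeLU, and
pointwise reduction back to C.  No positional encodings are used — the
convolutional projections carry the spatial information.  The default stage
widths are {32, 64, 128, 256, 256} with {1, 2, 2} SCT blocks and {4, 8, 8}
heads in stages 3–5.

**Denoising decoder.**  Five 3×3 stride-2 deconvolution stages (widths
{256, 256, 128, 64, 64}), each followed by a 3×3 convolution, with layer
norm and GeLU throughout.  The first four stages fuse an encoder skip:
the encoder feature is gated by a squeeze-and-excitation block
(`se_block()`: global average pooling, a C→C/8→C bottleneck, sigmoid gate),
projected by a 1×1 convolution to the decoder width, and added.  Addition
(rather than concatenation) keeps the decoder's parameter budget small.
The head is a 3×3 convolution with one filter and linear activation;
outputs are clipped to [0, 1] at inference only.

**Segmentation decoder.**  Deliberately lightweight: five ×2 bilinear
upsamplings, each followed by a per-pixel linear decoder block
(`linear_decoder_block()`: LP to C/2 units, layer norm, GeLU, LP back to C)
with stage widths {256, 128, 64, 64, 32}, and a 3×3 convolution head
emitting K = 3 logits.  Softmax is applied in the loss and at inference,
never inside the network.

### Architecture reconciliation

The original description of this architecture leaves several details open
(one or two convolutions per early block, normalization placement, the skip
fusion mechanism, the exact decoder widths).  We fixed them by requiring the
build to reproduce, *by configuration alone*, all seven reference complexity
figures of the model family: the multi-task, segmentation-only and reconstruction-only variants,
both feature-fusion ablations, and both filter-size scalings.  The build
above matches every figure within ±0.5%, and reproduces the two
ablation increments exactly at 3-decimal precision: removing the SE gates
saves 0.022 M parameters and the whole segmentation decoder costs 0.104 M.
`count_parameters()` reports the exact integer count, the per-component
breakdown, and a MAC/FLOP estimate (convention: one multiply-add = 2 FLOPs,
stated in the report because the reference convention is not stated).

```{r counts}
count_parameters(esdm_model(esdm_config()))
```

## Losses

Training minimizes `L_c = L_D + L_seg` (`combined_loss()`), with no extra
weights.

The denoising term (`denoise_loss()`) is
`alpha * sum((I - Ihat)^2) + beta * sum((phi(I) - phi(Ihat))^2)` with
`alpha = 1`, `beta = 0.01`.  Both terms are *sums* over elements, not means
— the printed form of the objective — because the alpha/beta balance was
calibrated on sums; across a batch the per-sample sums are averaged.  The
feature extractor `phi` is pluggable (`feature_extractor()`): the default is
a small convolutional network with frozen, seed-determined random weights, a
deterministic, download-free stand-in in the spirit of random-feature
perceptual metrics; a pretrained perceptual callable can be supplied for
loss evaluation, and `beta = 0` reproduces the MSE-only ablation.  Which
layer of a pretrained network should feed the loss is not fixed by the
method; it is a configuration knob of the callable.

The segmentation term (`seg_loss()`) is soft-label cross entropy: pseudo
labels are imperfect, so the annotated class receives confidence 0.95 and
the remaining 0.05 is spread uniformly over the other classes
(`encode_soft_labels()`).  Logs are clamped at 1e-12.  Disabling a decoder
removes exactly its term, which is how the single-task ablations train.

## Data pipeline

`frame_average()` collapses the repetition axis by the per-frame arithmetic
mean — the high-quality denoising target.  `extract_patches()` crops
256 × 256 boxes at the protocol's transverse offsets ({0, 144} on
400-pixel intraoral frames, {0, 256, 344} on 600-pixel LSM03 frames);
coordinates are 0-based with half-open windows, so the printed range
"[0, 256]" has width exactly 256.  The axial window is anchored at the image
top, where the structural signal lives.  `make_dataset()` enumerates every
(frame, window) pair into (noisy, target, soft label) triples; the first
frame of each volume carries its manual mask, all others pseudo labels; the
train/validation/test split is drawn **by volume** so no volume straddles
roles.

Pseudo labels come through a teacher interface (`teacher_oracle()`).
Pre-trained segmentation networks of the kind that generate such labels in
practice are not redistributable here, so the default teacher is a
*corrupting oracle*: it
rebuilds the mask from boundary curves displaced by smooth seeded noise
(scale `jitter`) and resamples a fraction `flip_rate` of pixels uniformly
over the classes.  This gives a controllable label-noise level, which is
exactly what the soft-label machinery is meant to absorb; an external model
can be plugged in unchanged.

## The phantom

`generate_phantom()` builds the synthetic ground truth every test runs on:
a two-layer tissue under air, with smooth surface and epithelium–stroma
boundaries (low-pass-filtered seeded noise, slowly varying across frames),
per-class reflectivity decaying exponentially with cumulative attenuation,
a small additive noise floor, and — per repetition — an independent
unit-mean gamma multiplicative speckle field (shape k, variance 1/k),
clipped to [0, 1].  Masks are derived from the same boundary curves, so
label transitions coincide with reflectivity transitions exactly and the
per-A-line thickness is known by construction (`true_thickness_profile()`).

Defaults (256 × 256 pixels, 4 repetitions, surface at 40 px, epithelium
60 px, boundary amplitude 6 px with correlation length 25 px, reflectivity
0.04/0.32/0.55, speckle shape 4, noise floor 0.03) were chosen once for
testability: moderate layer contrast, speckle strong enough that averaging
visibly helps (single-repetition PSNR around 15 dB), and geometry that a
segmenter must actually learn.  No intensity statistics of the original
clinical data are published, so no claim of radiometric realism is made.
The phantom deliberately omits coherent point-spread effects, refraction,
shadowing and motion artifacts; what passing tests show is that the
*pipeline* — averaging law, losses, training dynamics, thickness recovery —
behaves correctly, not that clinical performance is reproduced.

Because the speckle is i.i.d. across repetitions, the pixel variance of an
NR-repetition average is 1/NR times the single-repetition variance — the
law that makes frame averaging a valid ground truth — and this is verified
by Monte-Carlo in the test suite (the 1/NR scaling survives clipping; the
absolute v/NR·I² level is additionally checked on a low-reflectivity
configuration where clipping is negligible).

## Thickness quantification

`measure_thickness()` counts, per A-line, the epithelium pixels as the
*longest contiguous run* of label 1 — robust to isolated flipped pixels in
pseudo or predicted masks, which a plain count would miscount — and converts
to micrometres with `tissue_coefficient()`: the in-air axial pitch
(8.74 µm/pixel) divided by the tissue refractive index (1.395), about
6.27 µm/pixel.  A-lines with runs shorter than `min_run` are flagged
missing and excluded from frame statistics.  `thickness_mae()` compares
frame-mean thicknesses between predicted and reference masks; frame means
are the desk-scale analogue of the per-region means a clinical evaluation
would report (whether those are pooled per A-line, frame or volume before
the error is taken is not specified in the source; frame means are our
choice, stated here).

## Training and inference

`esdm_train()` runs Adam (learning rate 0.001, batch 16 by default;
beta1 = 0.9, beta2 = 0.999, epsilon = 1e-7 — unstated in the source and
recorded in the manifest) with a fixed learning rate, computes the
validation combined loss after every epoch and keeps the weights with the
lowest value (checkpoint policy "best"; the same `L_c` is used for
selection since no other criterion is specified).  A run is fully
reproducible from its seed: weight initialization (Glorot uniform),
shuffling and every phantom/teacher draw derive from it, and the manifest
records the configuration echo, seeds, a content fingerprint of the inputs
and the loss trajectory.  GeLU uses the standard tanh approximation.

`infer()` crops each frame per the protocol, forward-passes the patches,
clips the denoised patches to [0, 1] and stitches them with unweighted
averaging where windows overlap (no full-frame reconstruction rule is
published; averaging is the symmetric choice).  Segmentation stitches the
softmax probabilities and takes the per-pixel argmax, ties broken toward
the lowest class index.  Pixels outside every window keep the input
intensity and the background label.

## Numerical choices and degenerate inputs

* Convolutions use TF-style "same" padding (stride 2 pads bottom/right).
* Attention subtracts the row maximum before the softmax; the scaling
  dimensionality is the per-head width C/heads.  The channel dimension is
  split across heads — the head-split shape as originally printed
  transposes tokens and channels, which we read as typographical, since the
  channel split is the standard contract and leaves parameter counts
  unchanged.
* Layer normalization uses eps = 1e-5 over the channel dimension.
* `psnr()` reports identical images as +Inf; `ssim()` defaults to the
  11 × 11 Gaussian window (sigma 1.5, k1 = 0.01, k2 = 0.03) of standard
  practice, with the printed global-statistics form available as a mode —
  the two agree when a single uniform window covers the image.
* A segmentation class absent from both masks contributes 1 to mDice/mIoU,
  so toy cases without background remain defined.
* Masks with no epithelium yield missing thickness, never zero.
* Infeasible phantom geometry (boundaries leaving the image) and
  out-of-bounds crop windows are rejected with errors naming the offender.

## Problem sizes used by the tests

The test suite exercises everything on deliberately small problems chosen as
the package's own desk-scale study conditions: gradient checks on 6 × 5
feature maps, metric oracles on ≤ 12 × 12 images, the speckle law on a
128 × 128 phantom with 32 repetitions, and a smoke training of the reduced
configuration (filters {8, 16, 32, 64, 64}, one SCT block and two heads per
stage) for 10 epochs on ~200 pairs of 64 × 64 patches from 16 phantom
volumes, evaluated on held-out volumes against their ground-truth masks.

## Limitations

The phantom is a statistical surrogate, not a physical OCT forward model;
results on it do not establish clinical performance, for which the original
private dataset would be required.  The pretrained perceptual loss and the
pretrained teacher are interfaces here — their published weights are not
redistributable — so the shipped defaults (random-feature surrogate,
corrupting oracle) reproduce the *mechanisms*, not the exact published
numbers.  Training is CPU-bound and single-device; the 200-epoch clinical-scale
training regime is far outside desk scale, and no attempt is made to
reproduce clinical-data PSNR/SSIM/mDice/mIoU values or inference-latency
benchmarks.
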