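# esdm — multi-task denoising and segmentation of oral OCT B-frames

Optical coherence tomography (OCT) can assess the oral mucosa
non-invasively, but a single B-frame is degraded by speckle, and the usual
fix — averaging several repeated scans of the same location — multiplies
the scan time and the risk of motion artifacts in hand-held intraoral
imaging.  Clinically, what matters is the thickness of the epithelium above
the stroma, which requires a per-pixel layer segmentation that is hard even
for experts.

This package implements an efficient segmentation-denoising model (ESDM):
a multi-task network that takes a **single-repetition** B-frame and
simultaneously

* reconstructs a low-noise image, supervised by the frame average
  `V̄ = (1/NR) Σ_r V_r` of NR repeated acquisitions, and
* predicts a three-class mask (background / epithelium / stroma), trained
  semi-supervised: one manually labelled frame per volume, pseudo labels
  elsewhere, absorbed by a soft-label cross entropy (confidence 0.95).

The network is a shared five-stage encoder — two strided convolution
blocks, then three stages of separable convolutional transformer (SCT)
blocks, whose query/key/value sequences come from a 1×1 convolution
followed by a 3×3 depth-wise convolution feeding multi-head attention
`softmax(QKᵀ/√d)V` — with two task heads: a deconvolution decoder with
squeeze-and-excitation-gated skip connections for denoising, and a
lightweight bilinear + linear-projection decoder for segmentation.
The training objective is

```
L_c = L_D + L_seg,   L_D = α Σ(I−Î)² + β Σ(φ(I)−φ(Î))²   (α = 1, β = 0.01)
```

with φ a pluggable feature extractor, and `L_seg` the soft-label cross
entropy.  Epithelium thickness follows from the mask as
`N_pixel × (8.74 µm/px) / 1.395` — the in-air axial pitch corrected by the
tissue refractive index, ≈ 6.27 µm/pixel.

Because the clinical dataset is private, the package ships a synthetic
layered-speckle phantom generator (two-layer geometry with smooth
boundaries, exponential depth attenuation, independent unit-mean gamma
speckle per repetition) with exact ground-truth masks, so the entire
pipeline — averaging law, training, metrics (PSNR, SSIM, mDice, mIoU) and
thickness recovery — is testable end to end on any machine.

## Worked example

```r
library(esdm)

# a small 4-repetition phantom volume with known layer geometry
ph  <- generate_phantom(phantom_config(width = 256, depth = 256,
                                       n_frames = 4, n_repetitions = 4,
                                       seed = 1))
avg <- frame_average(ph$volume)           # the high-quality target
psnr(ph$noise_free[1, , ], ph$volume$data[1, 1, , ])  # single repetition
#> [1] 15.37853
psnr(ph$noise_free[1, , ], avg[1, , ])                # 4-frame average
#> [1] 21.4187

# the full multi-task model and its complexity report
model <- esdm_model(esdm_config())
count_parameters(model)
#> Model complexity (input 256 x 256 x 1)
#>   trainable parameters: 7,690,544 (7.691 M)
#>     encoder          4,463,712
#>     denoise_decoder  3,122,717
#>     seg_decoder      104,115
#>   MACs: 12.07 G; FLOPs: 24.14 G (1 multiply-add = 2 FLOPs)

# thickness from a ground-truth mask frame
measure_thickness(ph$masks$labels[1, , ])
#> Thickness profile: 365.54 +/- 25.00 um over 256 A-lines (6.265 um/px)
```

The single-repetition frame sits ~6 dB below the 4-repetition average —
the gap the denoiser is trained to close.  The complexity report shows the
design's economy: the segmentation decoder adds only 0.104 M parameters to
the 7.6 M reconstruction network.  Training (`esdm_train()`), inference
with patch stitching (`infer()` / `predict()`), evaluation
(`evaluate_model()`) and the ablation variants (single-task, no-SE,
no-skip, scaled filters) are all driven by `esdm_config()` /
`esdm_train_config()`; see the methods vignette
(`vignettes/esdm-methods.Rmd`) for the models, assumptions and numerical
choices, and `inst/cli/esdm.R` for a command-line wrapper
(`simulate`, `preprocess`, `train`, `eval`, `infer`, `thickness`,
`complexity`).

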