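# mrisr

Super-resolution for real-time MRI in MRI-guided radiotherapy, with an
in-silico multi-leaf-collimator (MLC) tracking testbed.

Real-time cine MRI on an MRI-linac trades spatial for temporal resolution:
tracking a moving tumour at 4 Hz typically forces coarse matrices (e.g.
64 × 64 over a 400 mm field of view, 6.25 mm pixels). This package implements
the full workflow for recovering spatial resolution by single-image
super-resolution without giving up frame rate, and for quantifying what that
buys a beam-tracking system:

- **k-space degradation.** Paired training data are synthesised by
  transforming a high-resolution image to the spatial-frequency domain
  (orthonormal centred FFT), cropping the central `N/f` block, rescaling by
  `sqrt(M/N)` so constants are preserved, and reconstructing the magnitude
  image — the physically faithful low-pass degradation of a shorter MRI
  readout.
- **EDSR-style network.** A single-channel residual CNN: head convolution,
  `B` residual blocks (conv–ReLU–conv, residual scaling 0.1, no batch
  normalisation), tail convolution with a global skip, then one
  conv + pixel-shuffle stage per doubling (two for 4×). The per-image mean is
  subtracted before the network and restored after. At the baseline-large
  configuration (B = 32, F = 256) the 4× network has ≈ 43 million trainable
  parameters. Bicubic (Catmull–Rom, a = −0.5) and nearest-neighbour
  up-samplers are the conventional baselines.
- **Training.** Adam with a one-cycle learning-rate schedule minimises an
  edge-weighted L1 loss `mean|p−y| + λ·mean|∇p − ∇y|` (Sobel gradient
  magnitudes); inputs are generated inline per batch by random crop +
  k-space truncation, and the checkpoint kept is the epoch of minimum
  *validation* edge-L1. Staged curricula (2× base → 4× transfer → fine-tune)
  are supported via `transfer_scale()`.
- **Evaluation.** Percentile clipping (99.9%), min–max scaling to 0–4096,
  optional rigid registration (NCC, coarse FFT search + Nelder–Mead),
  reference-derived brain masking (Otsu + morphology), and masked NRMSE /
  SSIM / PSNR with paired t tests between methods.
- **Tracking simulation.** A sphere (radius ≈ 30 mm) moves on sinusoidal or
  breathing-like traces; frames are rendered, degraded, optionally
  super-resolved, template-matched (NCC), and drive a velocity-limited MLC
  aperture after the imaging-chain delays. End-to-end latency is the phase
  shift between sinusoid fits to the target and aperture traces (recorded at
  the 3.6 Hz EPID rate); geometric error is the RMSE between traces, raw and
  after removing the measured latency.

## Worked example

```r
library(mrisr)

hr <- gen_anatomy_phantom(phantom_recipe(seed = 1, matrix = 256))
lr <- kspace_downsample(hr, 4)
lr
#> <gray_image> 64 x 64, spacing 6.25 x 6.25 mm, range [0.01858, 3774]

labels <- gen_label_set(60, seed = 7, matrix = 64)
set.seed(11)
model <- build_edsr(edsr_config(scale = 4, n_resblocks = 2, n_feats = 8))
fit <- train_edsr(model, labels,
                  train_config("scale2_base", max_lr = 0.02, label_crop = 32,
                               batch = 8, epochs = 10, seed = 7))
fit
#> <edsr_fit> stage scale2_base: 10 epochs, best epoch 10 (val edge-L1 1802.61)
#>   train loss 16493.7 -> 2294.5, final val NRMSE 0.1631, SSIM 0.2339

tab <- evaluate_methods(gen_label_set(10, seed = 21, matrix = 64), fit$model)
summarise_evaluation(tab)$means
#>    method  nrmse  ssim psnr
#> 1 bicubic 0.0938 0.629 20.6
#> 2    edsr 0.0918 0.620 20.8
#> 3 nearest 0.1035 0.596 19.7

rep <- experiment_suite(c("none", "bicubic"), spec = phantom_spec(),
                        timing = chain_timing(),
                        mlc = mlc_spec(max_leaf_velocity = 400),
                        n_repeats = 2, seed = 3, duration = 16)
rep
#> <tracking_report>
#>   none     latency 0.341 +/- 0.000 s, RMSE 4.56 +/- 0.50 mm, corrected 1.70 +/- 0.14 mm
#>   bicubic  latency 0.353 +/- 0.000 s, RMSE 3.95 +/- 0.39 mm, corrected 0.79 +/- 0.04 mm
```

Reading the output: degrading a 256 × 256 image over a 400 mm field of view
produces 6.25 mm pixels; 4× up-sampling restores 1.56 mm. Even a toy 7,745
parameter network trained for a few seconds edges out bicubic interpolation
on range-normalised RMSE on held-out phantoms. In the tracking experiment,
up-sampling the tracked frames leaves the end-to-end latency essentially
unchanged (≈ 0.35 s either way — the imaging chain, not the up-sampler,
dominates) while the latency-corrected tracking error drops by roughly half,
because displacement reports are quantised at the tracking pixel pitch
(6.25 mm at 64 × 64 vs 1.56 mm at 256 × 256).

A command-line wrapper is installed at `inst/cli/mrisr`
(`degrade`, `infer`, `train`, `evaluate`, `track-sim`, `report`), reading
and writing NIfTI/CSV/JSON with pixel spacing carried in the headers.

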