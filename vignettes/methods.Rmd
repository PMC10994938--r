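---
title: "Methods: k-space degradation, edge-weighted super-resolution, and simulated MLC tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: k-space degradation, edge-weighted super-resolution, and simulated MLC tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its models and the design
choices behind them: what is computed, under which conventions, why those
conventions were chosen where several defensible ones exist, and what the
synthetic experiments do and do not demonstrate about real scanner data.

## The degradation model

MRI acquires the spatial-frequency domain (k-space) line by line, so a
shorter readout measures only the central, low-frequency block. The package
degrades a high-resolution magnitude image the same way:

1. orthonormal centred 2-D FFT (`fft_centered`), DC at 0-based index
   `floor(N/2)` per axis — a convention that keeps DC inside every centred
   crop for both even and odd sizes;
2. central crop to `[floor(N/2) - floor(M/2), floor(N/2) + ceiling(M/2))`
   per axis, `M = N / factor`;
3. coefficient rescale by `sqrt(prod(M) / prod(N))`;
4. inverse orthonormal FFT; the *magnitude* is returned, so outputs satisfy
   the nonnegativity of magnitude MRI.

The rescale in step 3 deserves a note: under orthonormal transforms a
constant image of value `c` has DC coefficient `c * sqrt(prod(N))`, so
cropping alone would change the reconstructed constant. The chosen factor
maps a constant to the same constant, keeping low- and high-resolution pairs
on one intensity scale — which is what makes the network's mean-shift
normalisation (below) well posed. The amplitude convention of k-space
truncation is not standardised across implementations; this one is declared
normative here and enforced by a brute-force DFT oracle in the tests
(explicit sums over output frequencies, all sizes up to 32, agreement to
1e-8). Field of view is an invariant throughout: `shape * spacing` is
preserved by the degrader and all three up-samplers.

Intensity pre-processing for evaluation follows the same fixed rules:
clipping at the 99.9th percentile (linear-interpolation quantile of the
flattened image — one explicit rule so the clip is reproducible), min–max
scaling to 0–4096, and a hard 4096 clamp for sources with extreme
outliers.

## The super-resolution network

`build_edsr()` constructs a single-channel residual CNN: a head 3×3
convolution to `n_feats` channels; `n_resblocks` residual blocks of
conv–ReLU–conv with the block output multiplied by `res_scale` before the
skip addition (no batch normalisation — at these depths normalisation costs
accuracy for super-resolution, and the residual scaling of 0.1 keeps the
unnormalised chain stable); a tail convolution with a global skip from the
head; one convolution to `4 * n_feats` channels followed by a 2× pixel
shuffle per doubling of resolution (two stages for 4×); and a final
convolution back to one channel.

The baseline-large configuration (32 blocks, 256 features) is pinned by its
parameter budget: the closed-form sum `(3^2 c_in + 1) c_out` over the layer
plan gives 43,080,705 trainable parameters for the 4× single-channel
network, i.e. ≈ 43 million, and the per-tensor count of a built model must
agree exactly. Grayscale normalisation is a per-image mean shift: the input
mean is subtracted before the network and added back to its output, for
training and inference alike — a zero network is then the identity on
constants, which the tests exploit.

Forward and backward passes are written in base R (im2col gather + BLAS
matrix multiply per convolution, with cached index maps); the backward pass
is validated against central finite differences during development and the
forward pass against a definition-level convolution oracle in the tests.
Inference is whole-frame — real-time inputs are 64 × 64, so tiling is
unnecessary.

The bicubic baseline is pinned to one dialect: Catmull–Rom kernel
(a = −0.5), half-pixel output centres (aligned corners off), replicated
borders. Library bicubics differ in all three choices, so the normative
dialect is asserted by an explicit 16-tap kernel-sum oracle.

Model bundles are one self-contained file (versioned magic header, JSON
config/metadata/manifest block, IEEE-double weight tensors in manifest
order). Serialization is deterministic — two saves are byte-identical — and
round trips are bitwise.

## Training

The loss is `mean|p − y| + lambda * mean|S(p) − S(y)|` where `S` is the
Sobel gradient-magnitude map (3×3 pair, symmetric padding). k-space
truncation specifically removes high-frequency content, so the penalty is
placed where the degradation hurts: edges. The exact edge operator is a
design choice; the Sobel magnitude is the simplest operator matching the
intent and `lambda` (default 1) is exposed so other operators or weights can
be swapped in. Training pairs are built inline per batch: a uniformly random
`label_crop` patch (default 192, giving 48 × 48 inputs at 4×) degraded on
the fly.

Optimisation is Adam under a one-cycle schedule (cosine warm-up over the
first 30% of steps from `max_lr / 25`, annealing to `max_lr / 1e4`; the
dialect constants are pinned for determinism). The staged peak rates are
1e-5 for the 2× base stage, 5e-5 for the 4× transfer stage and 1e-6 for
fine-tuning; these presume a large pre-trained model, so small fresh
desk-scale models override `max_lr` (the synthetic demonstrations use 2e-2).
The split is 90/10 by image, seeded; validation pairs are deterministic
centre crops so the validation loss is comparable across epochs. The
returned checkpoint is the epoch of *minimum validation edge-L1*, not the
last epoch, and NRMSE / SSIM / PSNR are logged per epoch. 2×→4× transfer
copies every shape-compatible tensor bitwise and freshly initialises only
the up-sampling stages (Kaiming-uniform from a recorded seed, so transfer
experiments are reproducible).

## Evaluation

`evaluate_methods()` reproduces the retrospective pipeline per label: clip,
scale, degrade, reconstruct with nearest / bicubic / network, optionally
rigidly register each reconstruction to the label, mask, and score. SSIM
uses an 11 × 11 Gaussian window (sigma 1.5), K1 = 0.01, K2 = 0.03, data
range `max(ref) − min(ref)`, valid-mode windows — SSIM is named in many ways
in the literature, so one dialect is fixed and checked against an
independent sliding-window implementation to 1e-8. PSNR is capped at 100 dB
on identity to keep logs finite. The brain mask is Otsu thresholding,
binary closing (disc radius 2), hole filling and the largest connected
component, computed once on the reference and applied jointly to every
method — masked metrics are provably indifferent to background pixels.
Registration maximises normalised cross-correlation (coarse rotation grid ×
FFT translation search, then Nelder–Mead refinement with bilinear
resampling); NCC is a declared stand-in where a deployed pipeline might use
any metric of a generic registration library, and is exposed accordingly.
Method comparisons use classical paired two-sided t tests, reported per
comparison without family-wise correction, with explicit handling of
zero-variance differences.

Whether masked or whole-image metrics are appropriate depends on the data;
the pipeline exposes `mask` on/off (masked by default, matching the
measured-volunteer use case where background dominates the frame).

## The tracking simulator

The simulated chain mirrors the deployed one: cine frames of a disc (the
central cross-section of a radius ≈ 30 mm sphere, drawn with one-pixel
linear partial-volume anti-aliasing) are rendered at the 256 matrix at each
frame's mid-exposure target position, degraded to the real-time matrix
(64 × 64 at 4 Hz), optionally up-sampled, and template-matched. The
template is built once through the identical imaging path, so degradation
blur cancels in the correlation.

Timing convention: with frame period `T`, the frame whose exposure starts at
`t_k` carries the target position at `t_k + T/2` (mid-exposure), and its
displacement command activates at `t_k + T/2 + D`, where `D` sums the
reconstruction, super-resolution, tracking and MLC delays. Commands are held
until the next frame (zero-order hold), which contributes a further `T/2` on
average, so the nominal end-to-end latency of the chain is `T/2 + D`. The
defaults (`D = 0.225` s at 4 Hz) give a nominal 0.350 s. The aperture is a
single centroid abstraction of the leaf bank, rate-limited at
`max_leaf_velocity` (default 25 mm/s, a typical MLC specification — the
value is configurable and unmodelled leaf-bank geometry is out of scope)
and updated at the control rate. Both traces are recorded at the 3.6 Hz
EPID rate after discarding a 2 s start-up transient (the aperture starts at
rest before the first command arrives).

Inside the chain, template matching reports *integer-pixel* positions by
default: a deployed tracker reports grid positions, and the resulting
displacement quantisation at the tracking pixel pitch (6.25 mm at 64 × 64,
1.56 mm at 256 × 256) is exactly what super-resolution buys the tracker.
`template_match()` itself defaults to parabolic sub-pixel refinement for
stand-alone use; the chain exposes the switch. Lost targets (peak NCC below
0.5) hold the last displacement — the safest deterministic policy.

Latency is estimated by least-squares sinusoid fitting: amplitude,
frequency, phase and offset on the target trace (FFT peak → dense frequency
grid → bracketed polish; the residual surface is multimodal in frequency,
so a golden-section search alone is unreliable), then a fit with frequency
fixed on the aperture trace; the phase difference over `2*pi*f`, wrapped to
`[0, 1/f)`, is the latency. A fit residual above 50% of the trace variance
raises an error rather than returning a meaningless phase. Geometric error
linearly interpolates the aperture onto the target timestamps over their
overlap; the latency-corrected variant advances the aperture timestamps by
the measured latency first. For a pure-delay aperture these obey
`RMSE = A * sqrt(2) * |sin(pi * f * tau)|` and a vanishing corrected error —
both asserted numerically.

The breathing-trace generator is a statistical surrogate (per-cycle
amplitude and period jitter around a 4 s / 10 mm cycle, random-walk baseline
drift), since actual patient traces are not distributable. Consequently the
simulator's absolute RMSE values are not comparable to any measured system;
what is reproducible — and what the tests assert — are ordering properties:
latency is essentially independent of the up-sampling method, the corrected
error is non-increasing as the tracking grid is refined (64 → 128 → 256),
and simulating a genuinely high-resolution acquisition by inflating the
frame period inflates latency far beyond the super-resolution chain.

## Synthetic phantoms

Training and evaluation fixtures are 2-D ellipse composites: a head
outline, nested anti-aliased ellipses, thin elliptical annuli and oriented
sinusoidal stripe systems (fine, high-gradient structure for the edge
loss), mild smooth texture, three intensity palettes emulating T1-like /
T2-like / FLAIR-like contrast mixed uniformly, intensities in 0–4096.
Phantoms are chosen over anatomy renders deliberately: they are
deterministic per seed, have analytic ground truth for masks and centroids,
and carry enough edge statistics for desk-scale training. They do not mimic
field-strength-dependent contrast, coil sensitivity, acquisition noise
correlations or banding artifacts — so a network that beats bicubic on
phantoms demonstrates that the training machinery works, not that the
trained weights transfer to scanner data.

## Problem sizes and numerical choices

The test suite trains a 2-block, 8-feature 4× network (7,745 parameters) on
200 phantom pairs at 64 matrix (32-pixel crops) for 30 epochs — sizes chosen
so the whole demonstration, including its baseline comparison, runs in about
a minute while still leaving the network measurably ahead of bicubic on
held-out NRMSE and SSIM. Degenerate inputs are handled explicitly
everywhere: constant images raise degenerate-range errors in NRMSE/PSNR and
a warning in min–max scaling; all-zero references yield empty masks;
registration that fails to improve on the identity returns the identity
flagged; non-finite training losses abort with a diagnostic rather than
continuing. Ties in the zero-padding centring break toward the top-left;
the percentile is the type-7 quantile; all RNG flows through explicit seeds
(generation helpers save and restore the caller's RNG state).

## Known limitations

Motion is one-dimensional with rigid targets (no out-of-plane motion or
deformation); the MLC is a centroid abstraction, not 120 leaves; the
network trained here is desk-scale and makes no claim to the reconstruction
quality of a GPU-scale model; DICOM input is not supported (NIfTI is); and
the simulator's absolute error magnitudes depend on a synthetic breathing
surrogate, as discussed above.
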