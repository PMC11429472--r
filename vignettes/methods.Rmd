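---
title: "Multiscale prompt-driven fundus tumor segmentation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale prompt-driven fundus tumor segmentation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Tumor lesions in retinal fundus photographs — uveal melanoma above all —
differ from most medical-image targets in two ways: their area spans more
than an order of magnitude across patients (the smallest and largest lesions
in a typical clinical series differ by a factor of well over ten), and their
boundaries are irregular. A segmentation network therefore needs features at
several spatial scales at once, and its training signal should pay specific
attention to the lesion boundary.

`fundusseg` implements an encoder-decoder network designed around those two
constraints, together with everything needed to exercise it end to end
offline: a synthetic data generator, losses, metrics, a training loop and a
CLI.

## The model

**Input pyramid.** A `[3, H, W]` image (H, W divisible by 32) is expanded
into three scales: the image itself; a space-to-depth rearrangement with
block 4 (`48 x H/4 x W/4`, channel-replicated to 96); and a space-to-depth
with block 8 (`192 x H/8 x W/8`). Space-to-depth is a lossless bijection —
both pyramid levels reconstruct the input exactly, which the tests assert.
The channel counts 48 = 3·4² and 192 = 3·8² force this interpretation of
"segmenting the image into scales"; no information is discarded before the
encoder.

**Three-branch encoder.** Branch 1 applies a hierarchical windowed-attention
backbone (Swin-style, Tiny dimensioning: channels 96/192/384/768, depths
2/2/6/2, window 7, shifted on alternate blocks) to the raw image through a
4× patch embedding. Branches 2 and 3 apply ConvNeXt-style stages (Tiny
dimensioning, depths 3/3/9/3, V2-style blocks with global response
normalisation) to the two pyramid levels; their stems are 1×1 convolutions
plus layer normalisation so the first stage of each keeps its input
resolution, and branch 3 skips stage 1 entirely. All three branches end with
a `768 x H/32 x W/32` map. The `center_branch` switch swaps the attention
and convolutional roles, and single-branch ablations (attention-only,
convolution-only, and a residual-bottleneck fallback) are reachable by
configuration alone.

**Fusion.** The two side-branch maps are gated by squeeze-and-excitation
attention — sigmoid(1×1 conv of the global average pool), multiplied per
channel — and added to the centre map: `F = F1 + gate2(F2) + gate3(F3)`.
The two gates have separate parameters, and the gate is the single 1×1
convolution the architecture specifies — no hidden reduction bottleneck of
the kind classic squeeze-and-excitation uses. No nonlinearity precedes the
sigmoid.

**Decoder.** Four blocks of 1×1 conv → 3×3 transposed conv → 1×1 conv
restore resolution along the channel plan [384, 192, 96, 3], with GELU
between the convolutions inside a block. After each of the first three
blocks, the stage maps of every branch that reaches that resolution are
concatenated, projected by a 1×1 convolution to the decoder width, and
summed into the decoder stream (so the "sum" and "concatenate + adjust"
descriptions both hold). Four channel steps must bridge five resolution
levels (H/32 to H), so the last block upsamples by 4. A stride-4 transposed
convolution with a 3×3 kernel would leave 7 of every 16 output pixels with
no input contribution (the kernel is smaller than the stride), so the final
block uses a 4×4 kernel — every output pixel receives exactly one kernel
application; the stride-2 blocks keep the 3×3 kernel.

**Prompt dynamic head.** The fused map is pooled and classified by a small
MLP into benign/malignant. The class is written into the fixed template
`"it is a image of {lesion class}"` (kept verbatim, including its grammar)
and embedded by a frozen text encoder into 512 dimensions. The pooled
features concatenated with that embedding pass through a three-layer
controller that emits the 113 parameters of the final segmentation head:
three 1×1 convolutions, channel chain 3 → 8 → 8 → 1, ReLU between layers and
a sigmoid output. During training the prompt uses the ground-truth class
(teacher forcing); at inference it uses the predicted class. The default
text encoder is a deterministic hashing stub with the same interface and
output width as a CLIP text encoder, so the full pipeline runs without
downloads; a real CLIP encoder can be plugged in through
`make_text_encoder()`'s interface. Either way the encoder is frozen — it has
no trainable parameters here, and training verifies its outputs are
bit-identical before and after.

One initialisation choice matters: the controller's output bias is
initialised as a He-scaled random head (the weight matrix entries of each
head layer drawn with sd `sqrt(2/fan_in)`, biases zero) rather than zeros.
The bias acts as the default head that per-image modulation is added to;
with an all-zero start the generated weights are tiny and almost no gradient
reaches the decoder, which in practice freezes training in an
all-background state.

## Losses

Training minimises

    L = λ1·L_ce + λ2·L_dice + λ2·L_boundary_dice + λ_cls·L_cls

with λ1 = λ2 = λ_cls = 1 by default (the weights are exposed in
`loss_config()`, including a separate `lambda3` override for the boundary
term). `L_ce` is mean pixel binary cross-entropy; `L_dice` is the smoothed
Dice loss `1 − (2Σyp + ε)/(Σy + Σp + ε)` with ε = 1e−6 so empty masks are
well defined. `L_cls` is the 2-class cross-entropy of the auxiliary
classifier; it is part of the joint objective (no separate optimiser).

`L_boundary_dice` evaluates the same Dice form on morphological boundary
rings: each mask is dilated by an iterated 3×3 window-max and the original
subtracted, leaving the one-element-wide outer ring. Two details are
deliberate. First, the ring is computed as `dilate(m) − m`; the opposite
order is nonpositive everywhere and identically zero on binary masks, which
cannot be what a boundary loss intends. Second, dilation is a *max filter*
applied to the raw probabilities, not to a thresholded mask, which keeps the
term differentiable; its gradient routes to the per-window argmax.

## Training procedure

AdamW (decoupled weight decay 0.01, applied to matrices but not biases or
normalisation gains) starts at learning rate 2e−4 with batch size 12. The
rate is halved when the best epoch loss has not improved for 20 consecutive
epochs; training stops when the rate reaches 5e−7 or after 50 consecutive
epochs without a halving. The schedule runs on the training loss at epoch
granularity — no validation split is carved out of the training set.
Augmentation applies hue/saturation/brightness jitter to the image, and
translation, zoom, rotation, aspect change, flips and 90° rotations to image
and mask jointly (mask resampled nearest-neighbour so it stays binary).

Evaluation binarises the sigmoid output at 0.5 and reports per-image IoU and
Dice (related by Dice = 2·IoU/(1+IoU)), averaged over images with the sample
(n−1) standard deviation. An image whose reference and prediction are both
empty scores 1.0 on both metrics — a correct empty prediction is perfect.

## The synthetic dataset

Real fundus-tumor photographs with reference segmentations are private
clinical data, so the package ships a deterministic generator
(`generate_sample()`, `generate_dataset()`) that reproduces the statistical
structure the model targets rather than the appearance of pathology:

* a dark circular fundus field with a low-frequency illumination gradient
  and a handful of cubic-Bézier vessel-like curves (cosmetic only, and
  documented as non-clinical);
* exactly one connected lesion per image, drawn as a star-shaped region
  `r(θ) = R(1 + Σ_k a_k sin(kθ + φ_k))`, k ≤ 6, |a_k| ≤ 0.35 with Σ|a_k|
  capped at 0.6 so the region cannot pinch apart — irregular but connected
  boundaries without modelling pathology;
* lesion areas sampled **log-uniformly** over a configured fraction range,
  default 0.015–0.27 of the image area. Those bounds are the printed
  extremes of a real series (287,061 and 5,000,119 pixels on a 4304×4306
  frame), a ≈17-fold spread; the radius is rescaled after rasterisation
  until the realised fraction lands inside the range, so the area contract
  is exact, not approximate. (The same series is described elsewhere as
  spanning "about 12 times"; the generator exposes the range as
  configuration rather than resolving that discrepancy.)
* a benign/malignant label drawn with P(benign) = 0.4055, matching a
  103/151 class split; malignant lesions get stronger edge perturbation and
  a darker core so the image-level class is learnable from pixels, since no
  image-level definition of the classes exists for synthetic data.

Everything is a pure function of `(config, index)`: per-sample RNG streams
are derived from the master seed, and images are quantised to 8 bits before
being returned so PNG round trips are exact.

What passing tests on this data do and do not show: they demonstrate that
the architecture, losses, optimisation and evaluation machinery are wired
correctly and can fit segmentation structure across a wide lesion-size
range; they say nothing about accuracy on real fundus photographs, which
differ in texture, vessel morphology, lighting and pathology appearance.

## Numerical choices and problem sizes

* Dice smoothing ε = 1e−6; cross-entropy clipping 1e−7; layer-norm ε 1e−6.
* Max-filter ties route gradient to the first-found argmax (deterministic).
* Attention uses learned free-form per-window positional biases
  (`window² x window² x heads` per block), a strict superset of the usual
  relative-position table; masks handle shifted windows and padding.
* Weight init: truncated normal sd 0.02 throughout (the convention of the
  backbone families); controller output bias as described above.
* The package's tests exercise a desk-scale configuration — 64-pixel
  images, channels divided by 4, head width 8, window 4 — chosen so the
  full train/predict/evaluate cycle runs in minutes on one CPU core; the
  full-size 448-pixel geometry is verified with a single forward pass.
  The acceptance script trains on 16 synthetic images (80/20 split by id
  hash) at the same desk scale.
* The whole network, including its reverse-mode autodiff, is implemented in
  R on top of BLAS matrix products; every operator's gradient is verified
  against central finite differences in the test suite.

## Known limitations

* The synthetic generator is a statistical stand-in, not a renderer of
  pathology; models trained on it do not transfer to clinical images.
* The hash text encoder separates the two class prompts deterministically
  but carries no semantics; with it, the prompt pathway is an architectural
  conditioning mechanism rather than a source of language knowledge.
* Single-channel sigmoid output with a fixed 0.5 threshold (rather than a
  two-channel softmax) is a design choice; threshold sensitivity is not
  explored.
* Whether a skip connection should exist at H/32 (before the first decoder
  block) is unspecified in the source design; none is implemented.
* Pretrained backbone weights are not bundled; branches initialise randomly
  and a checkpoint hook (`save_checkpoint()`/`load_checkpoint()`) is the
  supported way to bring external weights.
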