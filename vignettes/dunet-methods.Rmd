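---
title: "DU-Net: models, training protocol and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DU-Net: models, training protocol and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dunet)
```

## The problem and the model

Plant-branch images for forage phenotyping contain three pixel classes with
extreme imbalance: a dark cloth background (most of the image), blob-like
leaves, and very thin stems and petioles (a few percent of pixels at most).
Two standard encoder–decoder families fail here in complementary ways.
Atrous-pyramid models (DeepLabV3+) aggregate multi-scale context at 1/16
resolution and recover detail through a single shallow decoder, which
fragments structures a few pixels wide. Classical U-Nets carry
full-resolution detail through skip connections but, lacking global context,
misread bright background speckles between leaves as leaf tissue under
high-light conditions.

DU-Net fuses both streams over one shared encoder:

* **Shared encoder.** A ResNet (18 or 34; VGG-16/19 also supported) with
  output stride 16: the final stage trades stride for dilation 2, the
  standard DeepLabV3+ convention. Stage outputs are exposed as tap points at
  strides 2, 4, 8, 16, 16.
* **Atrous-pyramid branch.** The full DeepLabV3+ head on the deepest tap:
  a 1x1 convolution, three 3x3 atrous convolutions at rates (6, 12, 18),
  and a global-pool branch, concatenated (5 parallel branches) and projected
  by a 1x1 convolution; the decoder upsamples to stride 4, concatenates a
  1x1-reduced low-level tap, and refines with two 3x3 convolutions.
* **U-Net branch.** A double 3x3 convolution block applied to the raw image
  at full resolution, plus a skip decoder that repeatedly upsamples,
  concatenates an encoder tap (every tap except the deepest), and applies a
  double convolution.
* **Fusion head.** Both branch outputs are brought to input resolution by
  bilinear upsampling, concatenated, and reduced by one 3x3 convolution and
  a 1x1 convolution to per-class logits. Labels are per-pixel argmax, ties
  broken toward the lowest class index.

**Width scaling (the n/8 scheme).** Every canonical channel width C is
scaled to `floor(C * n/8)` (minimum 1) for an integer n between 2 and 8.
DU-Net-L is the resnet34 member at n = 4.

### Channel widths and the size table

The architecture's channel annotations had to be fixed as part of this
implementation. The pinned values (at n = 8) are: ASPP pyramid and
projection 192; low-level reduction 48; ASPP decoder convolutions 96 and 64;
U-Net-branch top block 32; skip-decoder blocks 128, 48, 32, 32; fusion
convolution 32. Together with the encoder conventions below, DU-Net-L then
counts 6,354,283 parameters = 25.42 MB, and the pinned baseline U-Net counts
34,513,475 = 138.05 MB, reproducing the family's reference sizes under the
convention `size = params x 4 / 1e6` (32-bit weights, decimal megabytes).
Two remarks on this choice. First, the size match is the validation
instrument: among common conventions for the baseline U-Net (transposed vs
parameter-free upsampling, normalization or none, biased or unbiased
convolutions) exactly one variant reproduces 138.05 MB — parameter-free 2x
upsampling followed by a channel-halving 3x3 convolution, biased
convolutions, no normalization — and that variant is pinned. Second, among
width assignments that reproduce 25.42 MB we deliberately chose one that
keeps the full-resolution layers narrow and puts capacity in the cheap deep
layers: the lightweight variant exists to cut deployment cost, and
full-resolution convolutions dominate CPU inference time.

Batch normalization lives inside residual blocks only (the conventional
ResNet placement); stem, VGG, branch and head convolutions are bias-only.
Normalization parameters (gamma, beta) are counted; running statistics are
not. The layer table (`architecture_summary()`, `audit_model()`) reports
every layer with kind, output shape and exact parameter count; activation
functions are omitted as they carry no parameters.

### CBAM variant

`attach_cbam()` inserts a convolutional block attention module after each
residual stage: channel attention (a shared two-layer MLP over global
average- and max-pooled channel vectors, sigmoid gate), then spatial
attention (a 7x7 convolution over channel-pooled mean and max maps, sigmoid
gate). Gates are multiplicative and shape-preserving; saturating every gate
at 1 reproduces the plain network exactly, which the tests exploit as an
equivalence check.

## The numerical engine

No deep-learning framework is assumed: convolution, batch normalization,
max pooling, bilinear resizing, backpropagation and Adam are implemented in
the package, with the heavy kernels in C++ (RcppArmadillo). Stride-1
convolutions use an offset-GEMM formulation — one GEMM against a weight
matrix whose columns enumerate kernel offsets, followed by shift-adds —
which avoids materializing the 9x-larger im2col matrix; strided convolutions
fall back to classic im2col. Convolution arithmetic runs in single
precision (the models are 32-bit), with double-precision storage on the R
side; gradient tests therefore use relative tolerances of 1e-2 to 5e-2
against central finite differences. Weights are He (fan-in) initialized;
all randomness (initialization, shuffling, augmentation, scenes) flows from
explicit integer seeds, and two runs from the same configuration and seed
are bit-identical on the same machine.

## Metrics and losses

Accuracy is pooled pixel accuracy (correct pixels over total pixels;
whether to pool over the test set or average per image was unspecified —
we compute pooled values by default and per-image rows in `evaluate_masks()`).
Per-class IoU is `TP_i / (TP_i + FP_i + FN_i)`; mIoU averages the K = 3
classes. A class with an empty denominator (absent and never predicted)
contributes IoU 1 — an absent class perfectly predicted; real test sets
always contain all three classes, so the convention only matters for tiny
fixtures. Cross-entropy is the mean negative log softmax probability of the
true class. The Dice loss is the soft per-class formulation averaged over
all classes with smoothing s = 1, and the combined loss defaults to weights
(1, 1); the loss names were given without formulas, so these defaults are
documented and configurable.

## Training protocol

Batch size 5 (final short batch kept), Adam with initial learning rate
0.001, cross-entropy by default, optional per-epoch decay
`lr = 0.001 x 0.95^epoch` (0-based). The test set is evaluated every epoch
so the protocol's model selection — the five highest-accuracy epochs of each
of five seeded repetitions, 25 parameter sets in total — has the records it
needs; note this conflates test and selection sets, which we reproduce as
reported rather than repair it. Validation loss is monitored but drives no
decision. Checkpoints are RDS files; save/load/predict is bit-identical.

## The synthetic scene generator

The generator emulates the statistical structure of branch photographs on
dark cloth, not their photometry: a curved stem polyline (default 3 px wide
at the 96x160 test canvas, scaling with canvas height), petioles leaving the
stem at 50-80 degrees carrying trifoliate clusters of three rotated
ellipses (semi-axes roughly 7-11 x 4-7 px), a background at intensity 0.06
with smooth cloth texture (sd 0.02), distinct class colours (green leaves
with per-leaflet brightness variation, pale brown-green stems), a vertical
illumination gradient and sensor noise (sd 0.015). The high-light regime
lifts the background by 0.10 and scatters bright speckles preferentially in
background gaps between leaflets — the stimulus for the
background-between-leaves confusion; illumination never changes the mask.
Class fractions obey background >> leaf >> stem by construction.

What passing tests on this data do and do not show: they demonstrate that
the architecture, losses, optimization and bookkeeping are correct and that
the model can learn thin-structure segmentation under class imbalance; they
do not certify accuracy on real photographs, whose colour distributions,
occlusions, annotation noise and leaf morphology are far richer.

## Benchmark problem sizes

The package's standing benchmark trains DU-Net (resnet34 encoder) at width
2/8 on 200 scenes of 96 x 160 (divisible by 32, as the encoder requires) for
20 epochs with the reference protocol and evaluates 20 held-out scenes; it
reaches mIoU at or above 0.90 and pooled accuracy at or above 0.97, with the
class-imbalance signature background > leaf > stem in per-class IoU. These
sizes are the package's chosen desk-scale conditions — large enough for the
imbalance pattern to appear, small enough to run routinely on one CPU.
The acceptance script runs a lighter variant (120 scenes, 15 epochs) plus
the exact size accounting and augmentation counts.

## Augmentation

Strategy 1 composes, per draw, flips, scaling (0.8-1.2), translation
(up to 10 percent), rotation (up to 25 degrees) — applied identically to
image and mask, the mask via nearest-neighbour with background fill — and
image-only colour operators: brightness (within 20 percent), hue/saturation
(within 10 percent), contrast (0.8-1.25), Gaussian blur (sd up to 1.5 px)
and Gaussian noise (sd up to 0.02). The operator set is prescribed; the
magnitudes are package defaults, configurable. Ten draws per source turn
250 images into 2,500. Strategy 2 takes five crops per source (1,250 from
250), each chosen among candidate windows to minimize the background
fraction (or centered on random stem pixels under the alternative rule), and
applies no colour operators. Per-draw randomness is counter-based — a seed
derived from (base seed, image index, draw index) — so results do not depend
on execution order. Every transform record can be replayed on the source
mask and reproduces the output mask exactly.

## Annotation conversion

Polygons use continuous 0-based coordinates with the pixel at row r, column
c centered at (c - 0.5, r - 0.5). Rasterization is scanline even-odd fill
with a half-open vertical rule, so shared edges are counted once; a pixel
belongs to a polygon when its center is inside. Later polygons overwrite
earlier ones (labelme conversion behaviour); "branch" maps to 1, "leaf" to
2, background 0. Masks are stored as single-channel 8-bit PNG holding the
class integers directly (the installed PNG writer does not support palettes,
so a separate colourized preview writer serves visual inspection).

## Known limitations

* CPU-only and single-device; determinism is promised per machine, not
  across BLAS builds.
* Single-precision convolution cores: outputs match double-precision
  references to about 1e-6 relative, not bitwise.
* The generator's schematic colouring makes the task easier than real
  imagery; headline benchmark numbers are properties of the harness, not
  claims about field performance.
* JPEG input is not supported (PNG only); EXIF orientation and the full
  labelme feature set (lines, points, groups) are out of scope.
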