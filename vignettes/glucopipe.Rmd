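---
title: "Methods: simulating and classifying colorimetric glucose captures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and classifying colorimetric glucose captures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glucopipe)
```

`glucopipe` models the computational half of a smartphone colorimetric
glucose assay: an enzymatic GOD/POD reaction produces a pink quinonimine
complex whose absorbance is proportional to glucose concentration; a
phone photographs the reaction well; a processing chain and a CNN turn
the photo into one of 16 concentration classes (50–200 mg/dL in
10 mg/dL steps). This vignette explains each model, its assumptions,
the tunable parameters, and the design decisions taken where more than
one reasonable choice existed.

## The synthetic colour model

No measured RGB values exist for the assay at any concentration, so the
simulator is constructed from first principles rather than fitted: the
colour scale is physically plausible, but absolute colour values carry
no empirical authority.

Each channel $k \in \{R, G, B\}$ of the well colour follows Beer–Lambert
transmittance,

$$ I_k(c) = \mathrm{round}\!\left( I^{0}_k \cdot 10^{-\varepsilon_k \, l \, c} \right), $$

with background (white film) intensity $I^0_k$, per-channel absorptivity
$\varepsilon_k$ (1/(mg/dL)), path-length multiplier $l$, and
concentration $c$ in mg/dL. Absorbance is therefore directly
proportional to concentration, and the constraint
$\varepsilon_G \ge \varepsilon_R, \varepsilon_B$ encodes the pink
product (green light absorbed most). Defaults:

* `background = c(230, 228, 226)`. Deliberately below the 8-bit ceiling:
  the brightest lighting/location combination multiplies the scene by
  1.1, and a background near 250 would clip at 255, which both is
  physically wrong (auto-exposure avoids blown highlights) and silently
  destroys the illumination-invariance of the contrast stretch (see
  below).
* `absorptivity = c(4e-4, 2.65e-3, 1.2e-3)`, `path_scale = 1`. The green
  coefficient makes the 50→200 mg/dL green span cover ≈ 60% of the
  usable range below the 50 mg/dL value (168 → 67), i.e. adjacent
  classes sit 5–8 intensity units apart — separable, but not trivially
  so under capture noise.

## The capture campaign

The generator reproduces the structure of the physical campaign: 16
concentrations × 2 lightings × 3 locations × 3 camera profiles × 5
replicates = 1440 images, written as `dataset/<concentration>/*.png`
with a `manifest.csv` recording every image's condition and seed.

Lighting and location act photometrically: a scalar illumination gain
(natural 0.9, artificial 1.0; locations multiply by 0.9/1.0/1.1) and a
per-channel tint (natural light slightly warm). Camera profiles carry
the published optics of the three handsets plus synthetic white-balance
gains near unity and an additive sensor noise scale (σ = 2.5–3.5
intensity units; the paper-scale default, reduced to a third in the
low-noise small profile). Noise is added to the scene *before* the
gains — photon-like noise that scales with illumination — which makes a
pure scalar gain rescale signal and noise together.

Each rendered scene is a centred disc (or square) well on the white
film, plus four small dark corner squares imitating the device's
printed position markers. The markers are not detected or used for
registration (well localisation is out of scope; synthetic captures are
pre-framed); they exist because the downstream percentile stretch needs
a dark anchor. A two-level well/background scene would be normalised to
the *same* stretched image at any well intensity — the 1% quantile
lands inside the well distribution itself — erasing the concentration
signal. With a dark reference covering a few percent of pixels, the
stretch maps marker→0 and background→255, cancels the illumination gain
exactly, and preserves the well level linearly. This is, we believe,
also why contrast saturation works on the physical captures, which
contain dark device features.

Determinism: every image's noise seed derives from the master seed and
the image's condition *values* (concentration, lighting, location,
camera-name hash, replicate), never from positions in the configured
factor lists — so any subset of the design regenerates byte-identically
to the full campaign.

What the simulator does **not** model: lens vignetting and perspective,
JPEG compression (images are lossless PNG), auto-white-balance
adaptation, enzyme kinetics and incubation time, well meniscus and
inhomogeneity, hematocrit or sample-matrix effects. Synthetic results
therefore demonstrate that the pipeline recovers the signal its own
physics encodes; they are not evidence about physical captures.

## Preprocessing

Three deterministic stages, each re-quantising to 8-bit integers with
round-half-away-from-zero:

1. **Grayscale**: ITU-R BT.601 luma, $0.299R + 0.587G + 0.114B$ — the
   default of common imaging toolchains; no conversion coefficients are
   specified by the assay protocol.
2. **Contrast stretch**: the bottom 1% and top 1% of pixel values
   saturate to 0 and 255 and the interior maps linearly. Quantiles are
   linear-interpolation quantiles of the pixel multiset
   (`stats::quantile` type 7), computed **per image** — matching a
   single-image app workflow, not per dataset (flagged as a convention
   choice). A constant image is passed through unchanged with a warning
   rather than erroring, so blank frames cannot kill a batch.
3. **Resize** to the classifier input (100 × 100 by default, 32 × 32 in
   the small profile): separable bilinear interpolation with half-pixel
   centre alignment; nearest-neighbour is available for ablation. An
   image already at the target size passes through pixel-identically.

The order matters — quantiles are estimated on the full-resolution
multiset before interpolation smooths the histogram — and a regression
test pins the canonical order.

## The classifier

Architecture (configurable via `cnn_spec()`):
input → [conv → ReLU → batch-norm] × 2 → optional channel-wise softmax →
flatten → dense (+ dropout) → dense(16) → softmax.

* The default full-size profile (100 × 100 input, 16/32 filters of 3 × 3
  at stride 1 with same padding, 240 dense units, dropout 0.5) has
  76.8 M trainable parameters by the closed form
  $\sum (k^2 c_{in} + 1) c_{out} + \sum 2c + \sum (n_{in}+1) n_{out}$ —
  the flatten-to-dense matrix dominates. It exists to match the
  published architecture scale and is never trained in the tests.
* The channel-wise normalised-exponential stage after the conv stack is
  unusual; it is implemented faithfully as an optional layer, on by
  default in the full profile and off in the small profile (it
  compresses activations and slows small-scale training).
* The small profile (`cnn_spec_small()`: 32 × 32 input, 8/16 filters of
  5 × 5 at stride 2, 128 dense units, no dropout; ≈ 137 k parameters)
  is the desk-scale workhorse. Dropout is omitted there because at 12
  images per class regularisation noise outweighs any overfitting
  protection within a 15-epoch budget.

Training is mini-batch Adam (β₁ = 0.9, β₂ = 0.999) on softmax
cross-entropy, batch 32, with an optional cosine learning-rate decay.
The small profile uses initial rate 8e-3 with cosine decay over 15
epochs: without decay, short budgets oscillate between adjacent
concentration classes at the end of training; with it, held-out
accuracy is ≥ 0.9 across seeds. Ties at the softmax argmax break to the
lowest class index; inference disables dropout and uses batch-norm
running statistics, so prediction is deterministic.

**Input normalisation.** Processed images are scaled to [0, 1], centred
per pixel on the training-set mean image, and divided by one pooled
standard deviation; the statistics are stored in the model and applied
identically at inference. The centring removes the static scene
structure shared by every capture; the single pooled scale brings the
between-class signal to order one. A per-pixel scale was considered and
rejected: it inflates noise-only background pixels to unit variance,
which a flexible network memorises instead of the signal.

Numerical conventions: He-normal weight initialisation; batch-norm uses
biased batch variance with ε = 1e-5 and momentum 0.9 running statistics;
convolution is im2col + GEMM with zero padding ⌊k/2⌋ for "same";
cross-entropy guards log(0) with 1e-12; non-finite loss aborts with a
diagnostic rather than continuing. All randomness (splits, shuffling,
initialisation, dropout, fold assignment) flows through seeds derived
from one master seed via a mixing function of the consumer's integer
coordinates, so reruns are bit-reproducible.

Data handling: stratified 80/20 train/test split (per class, within one
item of the fraction); stratified k-fold cross-validation (default
k = 10) pooling each item's single held-out prediction into one
confusion matrix.

## Evaluation

From the pooled or held-out confusion matrix (rows = truth, columns =
prediction) the package derives one-vs-rest TP/FP/FN/TN per class and
the standard metrics; a zero denominator defines the affected metric as
0 (with a message) so macro averages stay computable. Summary
precision/recall/F1 are macro averages over the 16 classes — stated
explicitly because summary figures computed otherwise are not
reconstructible from per-class tables.

ISO 15197-style bands: a prediction is acceptable within ±15 mg/dL of
the reference below 100 mg/dL and within ±15% at or above 100 mg/dL
("equal to or greater than"); boundaries inclusive. The two rules agree
exactly at the threshold (0.15 × 100 = 15), so the band is continuous.
The predicted concentration is the numeric label of the argmax class —
classification, not regression. Range-stratified R² uses the identity
line, $1 - \sum (p_i - t_i)^2 / \sum (t_i - \bar t)^2$, matching the
band framing; the R² of a refitted regression line is available via
`r2_method = "fitted"`, as which convention applies is genuinely
ambiguous. A stratum with fewer than two distinct reference values
reports `NA`.

## Problem sizes

The test suite and acceptance script run at sizes a scientist would use
at the desk: the full 1440-image campaign is rendered at 400 × 400 (the
downstream resize makes native phone resolution irrelevant; the
manifest records it), and model training uses the small profile on the
leaner campaign (one camera, two replicates — 192 images at 64 × 64,
one-third sensor noise, 32 × 32 inputs, 15 epochs). A full-profile
100 × 100 training run of the 76.8 M-parameter network is possible with
this code but is not exercised by the tests.

## Known limitations

* The synthetic colour scale cannot be validated against measured well
  colours; only its monotone, Beer–Lambert structure is asserted.
* Class separability near 200 mg/dL is intrinsically tighter (the
  exponential compresses), mirroring the physical assay; small-profile
  errors, when they occur, are adjacent-class confusions — which is
  also why ISO compliance can be 1.0 while accuracy is below 1.
* The CNN is plain R: fast enough for the small profile (seconds) and
  correct at any size, but not a competitive engine for the full-size
  architecture.
* Cross-validation retrains from scratch per fold; k = 10 on the full
  campaign is a long run and is tested at reduced size.
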