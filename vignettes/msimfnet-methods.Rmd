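---
title: "Multi-scale input, multi-feature fusion networks for histopathology: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale input, multi-feature fusion networks for histopathology: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Breast-lesion classification from H&E stained histology images is
complicated by two properties of the data: diagnostic evidence lives at
several spatial scales at once (gland architecture down to nuclear
texture), and staining appearance varies strongly between laboratories
and scanners. `msimfnet` implements a patch-based pipeline built around
a convolutional network that addresses both: each image is rescaled to
four ratios (1, 0.5, 0.33, 0.25), each scale is cut into four
non-overlapping quadrants, and the resulting 16 patches — resized to
224 × 224 px and stain-normalized — are classified individually before
their probabilities are fused back into one image-level decision.

The 16 patches are pooled as independent 3-channel training samples
rather than channel-stacked. The parameter arithmetic of the
architecture forces this reading: the stem convolution has
7 · 7 · 3 · 64 = 9408 parameters, which only works for a 3-channel
input.

## The network

The backbone is a dense-connectivity design: a 7 × 7 stride-2 stem to
64 channels (3-px zero padding, normalization, ReLU, then a 3 × 3
stride-2 max pool), followed by four dense blocks of 6/12/48/32
composite layers. Each composite layer is
BN-ReLU-conv1×1(128)-BN-ReLU-conv3×3(32): a bottleneck of
4 × growth = 128 channels and a growth rate of 32 channels appended to
the block's running concatenation. Between blocks, transitions
(BN-ReLU-conv1×1 at compression 0.5, then 2 × 2 stride-2 average
pooling) halve both channels and spatial size. A final normalization
follows the last block. The channel recursion is

64 → (+6·32) 256 → 128 → (+12·32) 512 → 256 → (+48·32) 1792 → 896 →
(+32·32) 1920,

and the spatial chain for a 224-px input is 112 → 56 → 28 → 14 → 7.

The distinguishing element is multi-feature fusion: global average
pooling taps the feature map after each stage (widths 128, 256, 896,
1920), and the selected tap vectors are concatenated into one fused
descriptor (3200 features with all four taps) which passes through
dropout, a normalization over the descriptor, and a softmax classifier.
The single-tap baseline (`build_baseline()`) classifies from the
1920-wide final tap alone with a direct softmax head — the conventional
dense-network classifier used as the comparison model.

### The parameter ledger as a specification surface

`param_ledger()` computes every block's parameter count in closed form;
`model_param_count()` counts the values actually allocated by
`build_model()`. Both must agree for every tap subset, which pins the
accounting convention:

- convolutions are bias-free;
- a normalization layer contributes 4 accounting parameters per channel
  (gain, offset, and the two tracked statistics);
- the last dense block includes the trailing 1920-channel normalization
  (7680 parameters) in its total.

Under this convention one dense layer costs
`4·c_in + c_in·128 + 4·128 + 9·128·32 = 132·c_in + 37376` parameters and
a transition costs `c_in·(c_in/2 + 4)`; the 8-class full network totals
18,360,392 parameters. This convention was fixed by reconciling the
per-block totals exactly; it is asserted by the test suite and
recomputed by `scripts/acceptance.R`.

### Why the network is implemented in the package

No deep-learning framework is declared as a dependency: the network,
its backward pass, and the six optimizers of the tuning grid (SGD with
momentum, RMSprop, Adadelta, Adam, Adamax, Nadam) are implemented in R
with compiled im2col/col2im and pooling kernels, with the convolution
contractions running through BLAS. This keeps the architecture — the
package's core subject — fully inspectable, and makes the parameter
ledger and the "framework" count genuinely independent paths.

## Pre-processing choices

**Stain normalization.** The default method matches per-channel mean
and variance in a decorrelated logarithmic color space (the Ruderman
lαβ family): the image is mapped RGB → LMS → log → lαβ, shifted and
scaled to a reference mean/SD per channel, and mapped back with
clipping to [0, 1]. A stain-vector mode (`method = "macenko"`) is also
provided: optical densities are factorized into two stain vectors from
the leading plane of the OD cloud (1st/99th angle percentiles) and
concentrations are rescaled to the reference's robust maxima. The
mean/variance method is the default because it is the simplest standard
reading and is numerically safe on arbitrary input; the stain-vector
mode is behind a switch for users who want a physically motivated
factorization. The built-in reference (`default_stain_reference()`) is
synthetic — chosen to describe a typical well-stained field — so that
normalization never depends on any particular slide.

Normalization is applied **before** rescaling, matching the processing
order of the pipeline (normalize, then build the pyramid, then patch).

**Geometry.** Pyramid level sides are `round(ratio × side)` with
bilinear resampling (EBImage); the ratio list is taken literally as
(1, 0.5, 0.33, 0.25) — 0.33 is not treated as 1/3, which is immaterial
after patch resizing but fixed for reproducibility. Quadrants are the
2 × 2 grid of `floor(side/2)` tiles in row-major order; an odd trailing
row/column is dropped. Every valid image therefore yields exactly
4 × 4 = 16 patches with (scale, quadrant) provenance.

**Augmentation.** Training-time transforms follow the usual histology
suite: horizontal/vertical flips, rotation, width/height shifts,
brightness, zoom, and slight Gaussian blur. Published descriptions of
such suites rarely fix the ranges, so the defaults here are moderate
values standard in histopathology work — rotation ≤ 30°, shifts ≤ 10%,
brightness ∈ [0.8, 1.2], zoom ≤ 10%, blur σ ≤ 1 px — all exposed in
`augment_config()`. Geometric transforms run on a reflection-padded
copy so borders are never filled with invented background. Augmentation
is applied on the fly per epoch (each epoch sees a fresh draw); a
materialized augmented dataset can be produced by calling
`augment_patch()` explicitly if needed.

## Training protocol

Patch labels inherit the source image's label. The loss is
cross-entropy on one-hot labels; with a 2-unit softmax head the binary
cross-entropy coincides with the categorical loss, so both config names
map to one computation. Defaults follow the best selected
configuration: Adam, learning rate 1e-4, dropout 0.5, batch size 32,
64 epochs. Two readings of the printed configuration table conflict
with the stated search grid: the table's "Batch Size" row lists an
optimizer name (treated as a typesetting slip; batch size defaults to
32 from the grid), and its epoch values 32/64 differ from the grid's
{30, 40, 50, 70} (the table's values win as the final selection).

Cross-validation (`cross_validate()`) uses patient-disjoint folds
whenever patient identifiers exist — the clinically defensible choice,
since patches of one patient must never straddle a fold boundary — and
selects the configuration with the highest mean validation accuracy.
Reported metrics are means over `trials` independent seeded runs.
Class imbalance is left uncorrected by default, with optional
inverse-frequency weights behind `class_weights`.

**Normalization statistics.** Batch-normalization layers track running
mean/variance with exponential averaging (momentum 0.9). After short
desk-scale runs those statistics still reflect early weights, which
degrades inference-mode accuracy badly even when training-mode accuracy
is perfect. `train_patchwise()` therefore ends with a statistics
refresh (`recalibrate_bn()`): three forward-only passes over the
training data with a faster-tracking momentum, the usual "precise
statistics" correction. Weights are untouched.

**Degenerate batches.** A trailing batch of size one is folded into the
previous batch, since normalizing over a single sample is degenerate.

## Patch-to-image fusion

Three voting rules fuse the 16 patch probability vectors of one image:
majority (modal patch argmax), maximum (label of the single highest
patch probability), and sum (argmax of summed vectors). All ties are
broken by a fixed malignancy priority — most malignant class first:
Invasive, InSitu, Benign, Normal for ICIAR-style data; DC, LC, MC, PC,
A, F, TA, PT for BreakHis-style data. The priority applies inside the
maximum rule as well (two patches sharing the top probability), since
the priority governs the final outcome globally. The implementation is
verified against exhaustive enumeration over a 0.25-step probability
grid for up to 3 patches and 3 classes.

Per-class sensitivity and specificity are one-vs-rest; metrics with a
zero denominator are reported as `NA`, never silently 0.

## Paired model comparison

`mcnemar_standardized()` implements the continuity-corrected
(standardized) McNemar test on the 2 × 2 correct/incorrect
cross-tabulation of two models: statistic
`(|n12 − n21| − 1)² / (n12 + n21)` against chi-square with 1 degree of
freedom. Among the common McNemar variants, only the
continuity-corrected form reproduces both published p-values from the
printed tables (0.7353 → p ≈ 0.39 and 3.0637 → p ≈ 0.08), which fixes
the convention. The test errors when there are no discordant pairs.

## The synthetic data generator

`generate_dataset()` writes seeded toy datasets in the BreakHis-style
tree (class/patient/magnification encoded in SOB_* filenames), the
ICIAR-style per-class folders, or a generic labeled tree, so the
readers, splitters and training code run unchanged without any
external download. Textures are Poisson-scattered Gaussian "nuclei"
blobs on an H&E-like tinted background with per-image multiplicative
stain jitter (±5%) to exercise normalization.

Defaults — the standard desk-scale conditions used by the tests — are
2 classes (adenosis-coded benign vs ductal-carcinoma-coded malignant),
3 patients per class, 4 images per patient at a single 40×
magnification, 256 × 256 px. The image size keeps the smallest pyramid
level at 64 px and generation cheap; class blob rates double between
adjacent classes (40 · 2^(k−1)), which keeps mean blob counts at least
3σ apart for any number of classes, and class tints interpolate from
eosin pink toward a hematoxylin-leaning purple. A depth-1 logistic
model on mean intensity and blob count already solves this task (the
suite asserts ≥ 90% patch accuracy), so pipeline-level accuracy checks
measure the pipeline, not the data.

What the generator does **not** emulate: realistic nuclear morphology,
gland architecture, inter-patient texture correlation, scanner noise,
or any magnification-dependent content (all magnification folders of
one patient receive independent renders). Passing the desk-scale
checks therefore demonstrates that the pipeline is wired correctly and
can learn separable low-level statistics — it says nothing about
accuracy on real histology, which requires the external benchmark
datasets and full-scale training.

## Desk-scale configuration

The test suite and worked examples run a reduced configuration chosen
once: block repeats [2, 2, 4, 2] with all four taps, network input side
64 px, learning rate 1e-3 (a value inside the assessed grid, better
suited than 1e-4 to training from scratch for a handful of epochs),
batch size 32, 5 epochs, no augmentation, seed fixed. On the default
synthetic dataset this reaches perfect patch-wise training accuracy and
≥ 90% patch accuracy on the held-out patient, and all three voting
rules recover 100% image-wise accuracy. The full-size 224-px, 8-class
network is built and run forward once to verify the 3200-wide fused
descriptor and the printed parameter ledger; full-scale training is
out of scope by design.

## Known limitations

- Single-threaded CPU training only; the implementation favors
  inspectability over speed and is not meant for the external
  benchmark datasets at full scale.
- `init = "pretrained"` restores package-format checkpoints; no
  ImageNet weights are bundled or downloaded.
- Stain normalization assumes a mostly-stained field; images dominated
  by background glass will push the Reinhard statistics toward the
  background.
- The 201/205/210 "number of layers" presets are interpreted as
  backbone-depth variants; only the 205 reading (201-layer backbone
  plus 4-stage fusion head) is pinned by the ledger, and the exact
  layer allocation of the 210 variant is not modeled.
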