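---
title: "Weakly supervised gland segmentation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weakly supervised gland segmentation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Gland morphology in H&E-stained colorectal sections carries diagnostic
information, but pixel-accurate gland masks are expensive to annotate.
`maaseg` implements a two-stage weakly supervised segmentation pipeline
that needs only *image-level* labels: for each 112×112 patch cropped from
a whole-slide image, a two-bit vector saying whether the patch contains
any gland tissue and whether it contains any background (stroma).

Stage 1 trains a classifier on these bits, extracts class activation maps
(CAMs), and refines them into per-pixel pseudo-labels. Stage 2 trains an
ordinary segmentation network on those pseudo-labels with a loss that
down-weights unreliable pixels. Whole-slide predictions are obtained by
stitching overlapping patch predictions back together.

## Preprocessing: tiling and labels

Whole-slide images are cropped into 112×112 patches at stride 56 (50 %
overlap). Along each axis, window starts are the multiples of the stride,
plus a final start clamped to `dim − 112` so the image is fully covered;
for a 775×522 image this yields 13×9 = 117 patches. The patch label is
`gland = 1` iff any mask pixel inside the patch is gland, `background = 1`
iff any is background. At evaluation time, per-patch scores are stitched
by averaging overlapping pixels.

A note on the count formula: a closed-form expression of the per-axis
count as `ceil((dim − 112)/56) + [dim mod 112 ≠ 0]` agrees with the
sliding-window enumeration for every dimension not divisible by 112
(including all three GlaS image sizes) but yields 0 for an exact-fit
112×112 image; the enumeration (with clamped tail) is what the package
implements, and a property test checks the agreement on 1000 random
sizes.

## Stage 1: hierarchical encoder and multi-level attention fusion

The encoder is a six-layer hierarchical vision transformer. Each layer
consists of an overlapping patch-merging step (a strided convolution
whose kernel exceeds its stride: 7×7/stride 4 at layer 1, 3×3/stride 2
afterwards) followed by two repetitions of (efficient self-attention,
Mix-FFN). Layer *i* outputs a feature map at 1/2^(i+1) of the input
resolution — 1/4 … 1/128 — with non-integer divisions resolved by ceiling
(padded convolutions), so a 112×112 patch yields maps of side
28, 14, 7, 4, 2, 1. There is no positional encoding; locality enters
through the overlapping merges and the 3×3 depthwise convolution inside
each Mix-FFN. Attention keys/values are spatially reduced per layer
(ratios 8, 4, 2, 1, 1, 1) to keep cost linear in the query count.

Features from layers 3, 5 and 6 — coarse localization, structural
completeness, boundary refinement — are bilinearly upsampled to the
layer-3 resolution, projected to a common channel depth by learned 1×1
projections, and summed element-wise. A 1×1 two-class head applied at
every position gives the score raster; global average pooling of that
raster gives the image-level logits, trained with per-class binary
cross-entropy against the two label bits (SGD, initial learning rate
0.002 with cosine annealing to 0, batch 16). The CAM is the head response
before pooling, rectified at zero and min-max normalized per class to
[0, 1]; a channel with zero range is set to all zeros so that downstream
thresholds remain meaningful.

### Initialization and normalization choices

Three choices matter a great deal at the small training scales this
package targets, and are worth recording:

* **Silent residual branches at initialization.** The attention output
  projection and the Mix-FFN contraction are zero-initialized
  (SkipInit-style), so the network starts as a purely local convolutional
  pyramid and the attention context grows in only where it reduces the
  loss. With ordinary initialization the classifier can satisfy
  image-level supervision with spatially delocalized context features,
  and the CAM — which is only *indirectly* supervised — stops tracking
  content position.
* **Color-passthrough merge initialization.** The first
  `min(3, cin, cout)` output channels of every merge convolution start as
  exact center taps of the corresponding input channels, so at
  initialization the feature pyramid literally contains a downsampled
  copy of the (normalized) image. The locally-correct solution — score
  glands where gland colors are — is then reachable by a small parameter
  change, and gradient descent finds it before memorization shortcuts.
* **Zero-initialized classifier head.** The fusion head starts at zero,
  so its first update aligns the two class directions with the
  correlation between fused features and the label bits — a direction
  determined by the data rather than by the initial draw. Without this,
  which of the two channels ends up carrying the localization signal is
  a run-to-run lottery.
* **Global-RMS stage normalization.** Each layer's output map is divided
  by the scalar root-mean-square of its entries. This keeps feature
  magnitudes comparable across depths (the fusion sums three layers)
  without per-token renormalization; a per-token layer norm at stage
  outputs amplifies low-variance tokens, and in practice the zero-padded
  border tokens then act as free "register" slots that soak up
  classification evidence and corrupt the CAM.

## Pseudo-labels, pixel affinity and refinement

CAM scores are turned into three-way confidence labels with thresholds
`beta_low = 0.3` and `beta_high = 0.6` (both comparisons closed): the
argmax class where the maximum score is at least `beta_high` (1 = gland,
0 = background), background where it is at most `beta_low`, and the
ignore value 255 otherwise.

Two conventions precede the thresholding. First, class-presence gating:
per-patch min-max normalization presupposes that both classes occur in
the patch; when the image-level classifier predicts exactly one class
present, every pixel of the patch belongs to that class by the meaning
of the label (a `[1, 0]` patch *is* gland everywhere), so the present
class's channel is set to full confidence and the other to zero. Second,
tile-level label maps are built by computing CAMs patch by patch and
stitching them back with overlap averaging — the same merge used for
predictions — which averages away single-patch normalization noise;
training pseudo-labels are refined at tile level and cropped back to
patches.

A small MLP learns pairwise semantic affinities. Each pixel's descriptor
is its fused multi-level feature vector concatenated with a learned
8-dimensional embedding of its own confidence label; the three-layer
perceptron scores the concatenated descriptors of a pixel pair, averaged
over both argument orders so the score is symmetric. Supervision combines the
confidence labels with local image consistency: the CAM scores are first
smoothed by pixel-adaptive refinement under the patch RGB (below), then
re-thresholded, and unordered pixel pairs within Euclidean radius `r = 8`
are positive when both of these combined labels agree (and neither is
255), negative when they disagree — so negative pairs concentrate on true
appearance boundaries rather than on raw CAM noise. The loss is the mean of `1 − sigmoid(A)`
over positives plus the mean of `sigmoid(A)` over negatives, so that
minimizing drives same-region affinities up.

Refinement then proceeds in two steps. First, pixel-adaptive refinement
(PAR) smooths the upsampled CAM under the patch RGB: each pixel's score
is replaced by a softmax-weighted convex combination of itself and its
8-neighbors at dilations 1, 2, 4, 8, with weights from negated RGB
distance (bandwidth 0.1 on unit intensities) and spatial distance
(bandwidth 6 px), for 10 iterations. Second, a random walk propagates
scores through the learned affinities: the transition operator is the
row-normalization of `A∘β + I` (element-wise Hadamard power β = 8, unit
self-loops), applied t = 4 times per class channel. The power and step
count matter: the propagation should be a short, sharp consolidation.
With a gentle power and many steps the off-diagonal row mass of the
operator dwarfs the unit self-loop and the walk degenerates into spatial
diffusion that erases exactly the boundaries the refinement is meant to
sharpen; β = 8 follows the affinity-propagation literature and t = 4
keeps the effective propagation radius within a few neighborhoods. Finally the
confidence thresholding is re-applied at patch resolution to produce the
pseudo-label mask (stored as PNG with values 0/128/255).

Working resolution: pair construction, affinity learning and the walk run
on a grid 4× finer than the CAM (28×28 for a 112 patch), with features
and scores upsampled bilinearly. At the raw CAM grid the radius-8
neighborhood would connect essentially every pixel pair and the walk
would degenerate to global averaging; at the 4× grid the neighborhood is
genuinely local.

Affinity optimization: the MLP uses leaky rectifiers (slope 0.01), SGD
with learning rate 0.01, momentum 0.5 and gradient-norm clipping at 5;
fused features are channel-standardized per patch before descriptors are
built, and during training each pixel's label code is replaced by the
"uncertain" code with probability 0.5. The dropout serves two purposes:
it prevents the head from collapsing onto the trivial
label-equality shortcut (which would make the walk merely confirm the
initial labels), and it trains the uncertain-label embedding that
inference-time pairs actually contain. Without the leaky units and input
standardization the head can converge, on some seeds, to a constant
output (a dead-ReLU optimum), in which case the walk blurs rather than
refines.

## Stage 2: segmentation with online easy-example mining

The segmentation network is a compact pyramid-pooling CNN: a strided stem
and one further downsampling stage (1/4 resolution overall) with a
residual block at each scale, pyramid pooling at bins {1, 2, 3, 6}
(adaptive average pooling, 1×1 projection, bilinear upsampling,
concatenation), a 3×3 fusion convolution, a 1×1 two-class classifier and
bilinear upsampling of the logits to input resolution. A deeper backbone
is a drop-in configuration change; the desk default favors CPU training.

Training minimizes the normalized loss: with per-pixel cross-entropies
`L` over the valid (non-255) pixels of an image, the weights are
`w = softmax(−L) / mean(softmax(−L))` — unit mean, low-loss (reliable)
pixels weighted above 1 — and the loss is the `w`-weighted mean of `L`
with `w` treated as constant during backpropagation. When an image's
valid pixels contain a single class, plain mean cross-entropy is used
instead. The softmax scope is per image by default (`oeem_scope =
"batch"` pools it over the batch); per image is the literal reading of a
per-map weight and is batch-size invariant. Losses are clamped at 50
before the softmax so extreme pixels cannot underflow everyone else's
weight to zero. Optimization is SGD at a fixed learning rate 5e-4
(batch 32, 10 000 iterations at full scale; desk runs scale these down).
Ignored pixels contribute nothing to the loss or its gradient, which a
finite-difference test verifies.

## The synthetic tile generator

Every stage is testable without any dataset download through a
deterministic generator of H&E-like tiles: ring-shaped glands — a
purple-ish epithelial ellipse ring around a pale lumen — placed by
rejection sampling (at most 100 attempts per gland, overlaps rejected) on
a pink stroma background, with optional per-channel Gaussian noise, and
the exact ground-truth mask. The same spec always renders bit-identical
output, and the placed ellipse parameters are returned so tests can bound
the expected gland area analytically.

The generator emulates the *geometry and palette* of gland histology: the
three tissue classes, ring morphology, gland scale relative to the patch
grid, and whole-slide-like tile sizes. It deliberately does not emulate
nuclear texture, stain variation, blur, or instance-touching glands; with
`noise_sigma = 0` the three classes are exactly three RGB points and thus
linearly separable. Passing the recovery study therefore demonstrates
that the pipeline's machinery — supervision flow, CAM extraction,
refinement, loss weighting, stitching — recovers structure when the
appearance model is easy; it does not demonstrate robustness to the
appearance variability of real slides, which is what the full-scale GPU
configuration and a real dataset are for.

## The desk-scale recovery study

`run_recovery_study()` fixes the package's standard validation
experiment. Its problem sizes were chosen once, as a compromise between
statistical meaningfulness and a single-CPU wall-clock of a few minutes:

* 9 training tiles of 224×224: three with two glands of radius 40–60
  (mixed patches), two with no glands (pure stroma), four with one
  near-circular gland of radius 95–108 (so large it necessarily covers
  the central patch of the tile). Tiled at 112/56 this gives 81 patches
  covering all three label combinations at every seed, mirroring the
  composition of gland-bearing datasets where glands range from a
  fraction of a patch to beyond it.
* CAM stage: tiny encoder preset (channels 8…48), 30 epochs, batch 8,
  learning rate 0.002, flips only (random crops are disabled here:
  with fixed labels a crop that removes the gland actively teaches the
  classifier to rely on context rather than content, which on small
  synthetic sets degrades CAM localization).
* Affinity head: 20 epochs over the patch set, at most 1200 pairs per
  set and patch per epoch.
* Refinement comparison: 20 fresh single-gland tiles drawn from the
  large-gland training regime; the refined pseudo-label's foreground IoU
  (over its labeled pixels) is compared with that of the raw thresholded
  CAM. The comparison deliberately stays on the pipeline's operating
  distribution: refinement propagates and sharpens workable initial
  labels, and cannot repair a CAM that is structurally wrong over a
  whole region — a limitation shared with the full-scale method.
* Segmentation: 500 iterations, batch 4; evaluated as stitched
  whole-tile foreground IoU against the true masks.

All randomness derives from one master seed via fixed offsets, so reruns
are bit-reproducible and different stages cannot alias each other's
streams.

## Evaluation

Foreground IoU `|X∩Y|/|X∪Y|` and Dice `2|X∩Y|/(|X|+|Y|)` are computed
per stitched whole image and summarized as mean ± standard deviation in
percent (sample standard deviation by default; population on request).
Dice relates to IoU by `Dice = 2·IoU/(1+IoU)`, which is also exposed as
`dice_from_iou()` and property-tested against the direct definition. Both
metrics are defined as 1 when prediction and truth are both empty; this
convention only matters for gland-free synthetic tiles.

## Numerical and degenerate-input conventions

* Bilinear resizing uses the align-corners convention (corner samples are
  preserved exactly); a constant map resizes to the same constant.
* A CAM channel whose rectified response has zero range normalizes to all
  zeros rather than NaN.
* `confidence_labels` reads its thresholds as closed bounds (0.6 is
  foreground, 0.3 is background).
* An all-255 pseudo-label mask is rejected (the loss is undefined), as is
  an empty pair set for the affinity loss.
* The random-walk operator always carries unit self-loops, so zero
  affinity rows are harmless and the operator is row-stochastic by
  construction.
* Cross-entropy probabilities are floored at 1e-300 before the log;
  mining weights clamp losses at 50 before the softmax.

## Known limitations

* The tiny presets under-fit real histology; they exist to make the full
  pipeline exercisable and testable on one CPU. Reproducing published
  GlaS-scale numbers requires the large presets, the real dataset and GPU
  training, which are outside this package's test surface.
* CAM spatial resolution is bounded by the layer-3 grid (1/16 scale);
  structures whose width is below one grid cell cannot be localized by
  the CAM alone, whatever the refinement does.
* The affinity head sees only fused features and label embeddings; when
  the initial CAM is structurally wrong over a whole region, refinement
  cannot repair it and at best leaves it unchanged.
* Gland instances are not separated; the output is a binary semantic
  mask.
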