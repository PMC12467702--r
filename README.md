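# maaseg

Weakly supervised semantic segmentation of glands in H&E histology
images, from image-level labels alone.

Pixel-accurate gland masks are the costly bottleneck of computational
pathology; per-patch *presence* labels are nearly free. `maaseg`
implements a two-stage pipeline that turns the cheap labels into a
segmentation model:

1. **CAM generation and refinement.** A six-layer hierarchical
   transformer encoder (overlapping patch merging, efficient
   self-attention, Mix-FFN; output scales 1/4 … 1/128) is trained on
   112×112 patches with two-bit labels `[gland present, background
   present]`. Features from layers 3, 5 and 6 are aligned
   (bilinear upsampling + 1×1 projection) and summed,
   `F_multi = Σ_{i∈{3,5,6}} F̃_i`, and a 1×1 head with global average
   pooling yields class activation maps. CAM scores are thresholded into
   confidence labels (argmax where max ≥ β_h = 0.6; background where
   max ≤ β_l = 0.3; ignore = 255 otherwise), a 3-layer MLP learns pixel-pair
   affinities on a radius-8 neighborhood (loss: mean 1−σ(A) over
   same-label pairs + mean σ(A) over cross-label pairs), and pseudo-labels
   are refined by pixel-adaptive smoothing (RGB + position kernels)
   followed by random-walk propagation through the row-stochastic
   operator `rownorm(A∘β + I)`.
2. **Segmentation with online easy-example mining (OEEM).** A
   pyramid-pooling segmentation CNN is trained on the pseudo-labels with
   the normalized loss: per-pixel cross-entropies `L` are re-weighted by
   `w = softmax(−L)/mean(softmax(−L))` (unit mean; reliable low-loss
   pixels count more), falling back to plain cross-entropy for
   single-class images. Ignored (255) pixels never contribute.

Whole-slide images are tiled into 112×112 patches at stride 56 and
predictions are stitched back by averaging overlaps. Evaluation reports
foreground IoU = |X∩Y|/|X∪Y| and Dice = 2·IoU/(1+IoU) per whole image,
as mean ± sd in percent.

A deterministic generator of synthetic H&E-like tiles (elliptical
epithelial rings with lumina on stroma, exact masks) makes every stage
trainable and testable on one CPU without downloading any dataset.

## Worked example

```r
library(maaseg)

# a whole-slide-sized image is covered by 13 x 9 = 117 patches
compute_patch_grid(775, 522)$n
#> [1] 117

# Dice implied by a mean IoU of 81.99 %
dice_from_iou(81.99, percent = TRUE)
#> [1] 90.1

# run the full two-stage pipeline on synthetic tiles
cfg <- list(seed = 3,
            out_dir = tempfile("maaseg_run"),
            synth = list(n_tiles = 2, width = 168, height = 168,
                         n_glands = 1, radius_min = 30, radius_max = 50),
            maf = list(epochs = 1, batch_size = 4),
            affinity = list(epochs = 2, max_pairs = 300),
            segmentation = list(iterations = 4, batch_size = 2))
res <- run_pipeline(cfg)
res$report
#> Segmentation report over 2 image(s)
#>   IoU : 4.30 +/- 0.60 %
#>   Dice: 8.24 +/- 1.11 %
```

The one-epoch settings above only demonstrate the plumbing — the report
prints the stitched whole-tile IoU/Dice of a nearly untrained model. The
package's actual validation experiment trains both stages properly at
desk scale:

```r
res <- run_recovery_study(seed = 0)   # ~10-15 minutes on one CPU
res
#> Synthetic end-to-end recovery study
#>   gland-bit classification accuracy: 1.000
#>   refined >= raw pseudo-label IoU on 18/20 held-out tiles
#>   pseudo-label foreground IoU: raw 0.349 -> refined 0.414
#>   final segmentation: IoU 0.892, Dice 0.942 over 9 tiles
```

meaning: the stage-1 classifier recovers the image-level gland bit on
every training patch, affinity refinement improves (or preserves)
pseudo-label quality on 18 of 20 fresh tiles — lifting mean foreground
IoU of the labels from 0.35 to 0.41 — and the final segmentation
reaches a mean whole-tile foreground IoU of 0.89 against ground truth,
from image-level supervision only.

A thin command-line front end over the same functions lives in
`inst/scripts/maa.R`:

```sh
Rscript inst/scripts/maa.R run-all --config cfg.yaml
Rscript inst/scripts/maa.R eval --pred masks/ --truth masks_gt/ --out report.json
```

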