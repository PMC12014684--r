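---
title: "Methods: a lightweight anchor-free fruit detector and its evaluation stack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a lightweight anchor-free fruit detector and its evaluation stack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its model, its numerical
choices, and what its tests do and do not establish.

## The model

The detector is a single-stage, anchor-free network in three parts.

**Backbone.** A stem of two standard 3x3 stride-2 convolutions is followed
by four stages of inverted bottleneck residual blocks (strides 1, 2, 2, 2),
whose last three outputs C3/C4/C5 sit at strides 8/16/32. Each block
computes

    y = HardSwish( f3(f2(f1(x))) + x_shortcut )

with f1 a pointwise expansion by the factor `e` (Hard-Swish after it), f2 a
depthwise KxK convolution at the block stride (Hard-Swish), and f3 a linear
pointwise compression; the identity shortcut is present exactly when
stride = 1 and the channel count is unchanged — there is no projection
shortcut, so a non-addable shortcut is simply omitted. Batch
normalization follows every convolution; the source text is silent on
normalization, but an unnormalized deep stack of this kind is not trainable
in practice, and normalization is the universal convention in this model
family. Hard-Swish is `x * ReLU6(x + 3) / 6`: identity above 3, zero below
-3, global minimum -0.375 at -1.5.

**Neck.** C3-C5 are projected to a common pyramid width by ghost
convolutions (half the maps from a standard 1x1 convolution, half from
cheap 5x5 depthwise transforms of the first half, concatenated primary
first, ratio fixed at 2). The bidirectional pyramid runs `bifpn_repeats`
rounds of top-down and bottom-up fusion over P3-P5 only (three detection
scales); every merge node computes the fast normalized fusion

    O = sum_i max(w_i, 0) * I_i / (sum_j max(w_j, 0) + eps),  eps = 1e-4

with learnable per-input weights, then a depthwise-separable 3x3
convolution. Upsampling is nearest-neighbour; downsampling is a stride-2
depthwise-separable convolution.

**Head.** Decoupled, shared structure but per-level weights. The
regression branch (two standard 3x3 conv-norm units and a 1x1 projection)
emits `4 x regmax` channels: a discrete distribution over `regmax` distance
bins per box side. `regmax` defaults to 16, the established convention for
distribution-style box regression; the glossed reading of regmax as a count
of predicted boxes is not consistent with a `4 x regmax` channel rule, so
the bin-count reading is implemented. The classification branch uses
depthwise-separable convolutions and emits one channel per class. Decoding
is per cell: class score = max sigmoid activation; side distance = the
expectation over the softmax bin distribution, times the level stride,
anchored at the cell center; boxes are clipped to the image; greedy
class-wise NMS (IoU 0.45; confidence 0.25 for prediction, 0.001 for
evaluation so the PR curve is fully sampled).

## Complexity accounting

FLOPs are multiply-accumulates, counted over the *output* spatial grid
(identical to the input-grid statement at stride 1, and the standard
convention at stride 2), excluding bias, normalization, and activations —
the magnitude convention of detection GFLOP tables. For a spec
(H, W, Cin, Cout, K, stride):

* standard: `H' W' Cin Cout K^2`
* depthwise: `H' W' Cin K^2`; pointwise: `H' W' Cin Cout`; separable = sum,
  a saving of exactly `1/Cout + 1/K^2` at stride 1.

Parameters are counted exactly (convolution kernels, biases where present,
normalization scale/shift, fusion weights); the analytic walk is asserted
equal to the sum of the real tensor sizes in the test suite, and the FLOP
formulas are asserted equal to a loop that literally counts kernel taps.
`relative_change(before, after) = 100 (after - before) / before`, rounded
to 3 decimals, reproduces ablation-table percentage statements.

## Loss and training

Cells are assigned to targets by a task-aligned assigner: candidates are
cells whose centers fall inside a target box; the alignment metric is
`score^0.5 * IoU^6`, top-10 per target, conflicts resolved by the larger
metric; soft class targets are the alignment normalized per target and
scaled by the target's best IoU. The loss is

    total = 7.5 * box + 0.5 * cls + 1.5 * dfl

with `cls` a binary cross-entropy against the soft targets over all cells,
`box` a complete-IoU loss on decoded boxes, and `dfl` a two-bin
cross-entropy pulling each side's bin distribution toward the true
distance. Weights and assigner constants are the YOLO-family defaults the
source invokes. The soft targets are constants of each step; the CIoU
gradient with respect to the four decoded distances is taken by central
differences (step 1e-3 px) of the closed-form value and chained
analytically through the softmax expectation — verified end-to-end against
numerical differentiation under a frozen assignment.

Optimization is plain SGD with momentum 0.937 and weight decay 5e-4
(convolution kernels only), batch 16, 200 epochs by default. Warm-up is
linear over 3 epochs: learning rate from 0 (bias parameters from 0.1),
momentum from 0.8; the per-epoch schedule is linear from `lr0` to
`lr0 * lrf`. The source states initial and final learning rates both 0.01,
so the default is `lrf = 1` (flat); a decaying `lrf` is configurable.
Training is deterministic given the seed (init, shuffling, augmentation);
the best checkpoint by validation mAP50-95 is retained.

## Data and augmentation

Datasets use the YOLO text dialect (`class cx cy w h`, normalized, one file
per image) with a YAML manifest; images are stored as portable pixmaps
because no raster-format package is available in the target environment
and PPM is lossless and text-capable. Splitting shuffles under a seed and
apportions by largest remainder, so 1250 images at 8:1:1 give exactly
1000/125/125. (A source table prints 877/187/186 for the same ratio — the
numbers are irreconcilable with 8:1:1 on 1250; the ratio is treated as the
specification and the splitter takes arbitrary ratios, so either partition
is constructible.) Augmentation is online: rotation up to +/-15 degrees and
isotropic scale 0.8-1.2 about the center (boxes re-enclosed from their four
transformed corners, clipped, dropped below 4 px^2), and HSV jitter with
gains (0.015, 0.7, 0.4) — the transform families are named by the source,
the magnitudes are the community defaults. Label count never increases
under augmentation.

## The synthetic world

The generator emulates the stated structure of orchard photographs —
lighting variation, branch/leaf occlusion, fruit stacking — not their
appearance. A scene is: a low-frequency green foliage texture (green
clearly dominant, so fruit pixels are color-separable by construction — a
property the label/render consistency test relies on); shaded near-circular
fruit discs (radial gradient, hue jittered in the orange-red band) placed
without mutual overlap unless the clustering branch fires
(`cluster_prob`, default 0.3), in which case fruits deliberately stack;
elongated branch- or leaf-toned strips drawn across fruits with
`occluder_prob` (default 0.3) up to `max_occlusion_frac` (default 0.5) of
the radius; and a global brightness factor from 0.6-1.3. A fruit whose
visible fraction falls below 0.25 is not labeled — an annotation-realism
floor, arbitrary but fixed. Scenes are bit-reproducible from
(params, seed); datasets derive per-image seeds from one master seed.

What a green test establishes: the pipeline reads, trains on, decodes, and
scores exactly this class of scenes, and the generator's labels agree with
its renders. What it does not establish: performance on photographs —
occlusion geometry, texture, lighting, and annotation noise of real
orchards are all richer than this model.

## Numerical choices and degenerate inputs

* "Same" padding everywhere: output spatial size `ceiling(input / stride)`.
* Kaiming fan-out init for kernels; normalization scale 1, shift 0; the
  classification bias starts at `-log(99)` so an untrained model predicts
  background nearly everywhere.
* IoU of degenerate (zero-area) boxes is 0; precision and recall use the
  0/0 -> 0 convention; AP is undefined without ground truths (such classes
  are excluded from means with a warning); the evaluation errors on an
  empty split.
* AP uses COCO-style 101-point interpolation; matching is greedy by score
  with at most one detection per ground truth; reported P/R sit at the
  best-F1 confidence on the pooled IoU-0.5 PR curve. None of these
  conventions are stated by the source; they are the ones its numbers were
  produced with in the YOLO evaluation stack.
* NMS ties break by score then original index, so output is stable.
* The empty-target batch yields zero box/distribution loss and a finite
  classification term.

## Desk-scale capacity check

Absolute published scores are out of reach without the source imagery, so
the training stack is validated by an overfit oracle fixed in advance:
50 epochs on 32 easy synthetic 256x256 scenes (large separated fruit, no
occluders) must reach mAP50 >= 0.9 on those images. The instantiation
(quarter-width backbone, one pyramid repeat, batch 8, flat lr 0.01) was
chosen for CPU runtime, about 5 minutes; the first full run reached
mAP50 = 0.994. This establishes that the loss, gradients, optimizer, and
decode cooperate — not that the architecture matches published accuracy.

## Known limitations

* CPU-only and small-scale by design; no mixed precision, EMA, mosaic,
  multi-GPU, or export formats.
* The autodiff tape covers exactly the operations this network needs; it is
  not a general framework.
* Batch-norm statistics come from small batches; evaluation uses running
  averages, so very short trainings can show a train/eval gap.
* The generator's photorealism gap above; single-class fixtures throughout
  the tests (the code paths support multi-class).
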