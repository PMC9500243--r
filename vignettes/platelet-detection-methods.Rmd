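---
title: "Detecting platelets in stained smears: model, training recipe, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting platelets in stained smears: model, training recipe, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Platelets (thrombocytes) are the smallest blood cells: 2--4 µm across,
anucleate, irregular in shape, and roughly one tenth the diameter of an
erythrocyte. Counting them in stained smear images is clinically useful but
hard for generic object detectors, because at typical magnifications a
platelet occupies only a handful of pixels and its stain value sits close to
the background. `plateletdetect` implements a YOLO-v3-style single-stage
convolutional detector specialised for this regime, natively in R: the
network, its loss, and backpropagation are built on an `im2col` + BLAS GEMM
kernel (`src/ops.cpp`), so the whole pipeline runs on one CPU with no
deep-learning framework.

## Model

The backbone is Darknet-53-shaped: a stem convolution followed by five
stride-2 subsampling convolutions interleaved with residual stages
Res1/Res2/Res8/Res8/Res4, every block a CBL (convolution + batch
normalisation + leaky-ReLU, negative slope 0.1 -- the Darknet convention;
the original description leaves it unstated). Feature maps therefore exist
at strides 4, 8, 16 and 32.

Two head layouts are provided:

* **baseline** -- the classic three-scale arrangement: top-down fusion
  starting from the stride-32 map, heads on the 13×13, 26×26 and 52×52 grids
  (at input 416).
* **improved** -- the small-target variant: the 13×13 head is dropped (its
  receptive field has already washed out platelet-scale texture) and a
  104×104 head is added. Top-down fusion starts at the stride-16 feature and
  descends through stride 8 to stride 4.

Design choices the source material leaves open, decided here once:

* The stride-32 backbone stage is *computed but unused* in the improved
  variant rather than removed. This keeps every backbone parameter shared
  between the two variants (asserted by a structural test) and would allow a
  shared pretrained backbone.
* The new stride-8→stride-4 fusion step reuses the standard pattern
  (1×1 lateral CBL, 2× nearest upsample, channel concatenation, five
  alternating 1×1/3×3 CBLs) with channel widths half of the 52×52 path's,
  mirroring how widths halve at every finer scale elsewhere in the network.
* `width_mult` scales all channel counts (rounded to multiples of 8, floor
  8). It exists so desk-scale tests can train a real network in minutes; at
  `width_mult = 1` the architecture is the full-size one.
* Head convolutions initialise their objectness biases to −4 so an untrained
  network starts out predicting "background", which stabilises the first
  epochs on grids with thousands of cells and a handful of positives.

Each head cell predicts, per anchor, `(t_x, t_y, t_w, t_h, objectness,
class logits)` decoded as `centre = (cell + sigmoid(t_xy)) * stride`,
`size = anchor * exp(t_wh)` (clamped to `exp(±10)`), and
`confidence = sigmoid(objectness) × sigmoid(class)`.

## Box similarity and the matching score

Plain IOU is zero for any disjoint pair, so as an assignment or loss signal
it goes flat exactly where a detector of tiny objects needs guidance.
Complete IOU (CIOU) subtracts two penalties from IOU: the squared
centre-to-centre distance normalised by the squared diagonal of the smallest
enclosing box, and an aspect-ratio consistency term `α·ν` with
`ν = (4/π²)(arctan(w_gt/h_gt) − arctan(w/h))²` and
`α = ν/((1−IOU)+ν)` (the canonical closed forms, which the source text names
but does not print; `α` is defined 0 when its denominator vanishes).

The anchor-matching score is the *sum* `CIOU + IOU`: 2 exactly at identity,
still informative for disjoint boxes, and strictly increasing as a distant
box slides toward the target. During target assignment both shapes are
centre-aligned at the origin so only the overlap and aspect terms act.

Degenerate (zero-area) boxes return similarity 0 instead of raising, so one
corrupt annotation cannot abort a batch evaluation.

## Training

* **Assignment** -- every ground truth is assigned to the anchor maximising
  the centre-aligned match score; the cell containing the box centre at that
  anchor's scale holds the single positive. Occupied slots fall through to
  the next-best anchor, preserving the one-positive-per-ground-truth
  invariant.
* **Loss** -- `box_weight · mean_pos(1 − CIOU(decoded, target))` +
  objectness binary cross-entropy + `mean_pos` class BCE. Predictions that
  are not positives but whose decoded box overlaps some ground truth with
  IOU above `ignore_threshold` (default 0.5, plain IOU) are excluded from
  the negative objectness term. The CIOU gradient is analytic and exact,
  including the dependence of `α` on IOU and `ν` -- the suite checks it
  against central finite differences at 1e-4.
* **Loss balance** -- the objectness BCE normalises positive and negative
  sums by their own counts and re-weights the negative mean by `neg_weight`.
  Defaults `box_weight = 5`, `neg_weight = 25` were fixed once during
  development: with ~10 positives against ~25,000 negative cells per batch,
  an unweighted mean-of-means leaves so little suppression pressure that
  near-duplicate boxes around each platelet keep high confidence, and an
  unweighted sum (the classic YOLO choice) swamps the positives early. The
  values are tunable per run through `train_config()`.
* **Learning rate** -- the published recipe states both a fixed drop
  (0.001 → 0.0001 after 50) and a per-iteration ×0.92 adjustment, which is
  self-contradictory if "iteration" meant optimisation step. We read
  "iteration" as *epoch* (100 steps at batch 4 over ~300 images would be
  under two epochs, implausible for convergence) and compose the two:
  `lr(e) = base(e) · 0.92^(e−1)`, `base = 0.001` for `e ≤ 50`, then
  `0.0001`. `lr_at()` implements exactly this and is tested pointwise.
* **Optimiser** -- unspecified in the source; Adam with default moments,
  the field's default for from-scratch small-scale training. No data
  augmentation (none is described).
* Defaults: 100 epochs, batch 4, NMS IOU 0.45, confidence 0.25 -- the
  published values.

## Evaluation

Greedy confidence-ordered matching at `eval_iou = 0.5` (the VOC convention;
the published 0.45 is the *NMS* threshold and is not reused here), one-to-one
per ground truth; TN is undefined for detection and reported as `NA`.
Precision, recall and F1 use the standard confusion semantics -- the printed
confusion-matrix layout in the source swaps labels in a way inconsistent
with its own formulas, so the formulas win. AP is the raw Riemann sum
`Σ P(k)·Δr(k)` over the pooled confidence ranking, with no 11-point or
all-point interpolation, matching the printed definition. One published
table row (P = 100%, R = 15%, F1 = 1%) contradicts the F1 formula (which
gives ≈26%); the package implements the formula and does not attempt to
reproduce that row.

## Synthetic smears

The generator (`smear_config()`, `generate_image()`, `generate_dataset()`)
emulates the *structure* of a stained smear, not its optics: a pale pink
background with a gentle illumination gradient and gaussian noise; large
(60--110 px) erythrocyte-like disks with paler centres that are rendered but
**unlabelled**, reproducing the hard-negative structure of real smears where
distractor pixel values sit close to the background; and 3--12 small
(6--16 px, ≈1/10 the erythrocyte diameter, mirroring the 2--4 µm vs ~25 µm
biological ratio) darker-purple elliptical blobs with random eccentricity
(≤1.8), rotation and a granular core -- the labelled platelets. Placement
resamples any blob whose tight box would exceed IOU 0.6 with an existing
label, keeping the task well-posed. Each image derives its own RNG stream
from `(seed, index)`, so datasets are reproducible element-wise. Default
dataset size is 412 images split 296/33/83, the reference corpus shape.

The `high_contrast` preset (160 px, darker platelets, fewer and fainter
distractors, less noise) defines the scaled-down training benchmark: it is
deliberately the *easy* end of the task so that ~20 CPU epochs of a
width-0.125 model can learn it. A green end-to-end test therefore
establishes that the implementation — assignment, loss, gradients,
optimiser, decode, NMS, evaluation — works as a system; it does **not**
establish clinical-grade accuracy, robustness to stain variation, focus
blur, overlapping cells, or anything about real microscopy data, and the
published APs on the private real-smear dataset are not reproducible here.

Images are written as binary PPM by default: the guaranteed R environment
has no PNG package, and PPM is a ~30-line dependency-free format; PNG/JPEG
are used automatically when the `png`/`jpeg` packages are installed.
Configuration files are JSON for the same reason (YAML accepted when the
`yaml` package is present).

## Numerical and convention choices

* Coordinates are continuous, 0-based, half-open; Pascal VOC's 1-based
  inclusive integers are converted at the I/O boundary. For non-integer
  coordinates the ±1 VOC shift costs at most one ulp per round trip;
  integer coordinates (the native LabelImg case) round-trip bit-exactly.
* Anchor k-means uses `1 − IOU` of centre-aligned shapes as its distance
  (the YOLO-family convention; plain Euclidean is available behind a flag),
  arithmetic-mean centroid updates, seed-sampled distinct initial shapes in
  canonical order (so results are invariant to input ordering), ties to the
  lowest cluster index, and area-sorted output. The published 9-anchor
  platelet set ships verbatim as `default_platelet_anchors()`; it cannot be
  re-derived without the original private dataset.
* Scale groups bind the smallest-area anchor triple to the finest grid.
* Batch normalisation uses batch statistics during training and running
  statistics (momentum 0.1) at inference; `eps = 1e-5`.
* NMS breaks confidence ties by decode order; evaluation matching consumes
  the best-IOU ground truth first.
* Zero-denominator metrics (no detections / no ground truth) are defined as
  0 with a note, so batch evaluation never aborts.

## Known limitations

* CPU-only and single-threaded by design; full-width training at input 416
  is possible but slow — the package targets method-level correctness and
  desk-scale experiments, not production training speed.
* The improved variant's new fusion path widths are an interpretation (the
  source figure does not print them); parameter counts therefore may differ
  from the original implementation.
* Whether the original work replaced the loss, the NMS criterion, or only
  the assignment score with CIOU+IOU is unstated; here the match score
  governs assignment, the localisation loss is `1 − CIOU`, and NMS and
  evaluation keep plain IOU.
* Single-class by default; the VOC reader preserves unknown class names so
  multi-class smears work, but nothing platelet-specific is claimed for
  them.
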