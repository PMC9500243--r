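# plateletdetect

Platelet detection in stained blood-smear images with a multiscale
single-stage convolutional detector, implemented natively in R.

Platelets are the smallest blood cells (2–4 µm, about a tenth of an
erythrocyte's diameter), and their count is a core part of every routine
blood examination. In smear images they are tiny, irregular, faintly stained
blobs — close to the hardest case for a generic object detector. This
package re-implements, as a tested R library and command-line tool, a
YOLO-v3-style detector specialised for that regime:

* **geometry** — boxes, IOU, complete IOU (CIOU), and the anchor-matching
  score `CIOU + IOU`, which keeps a usable gradient even between disjoint
  boxes (`iou()`, `ciou()`, `match_parameter()`, `pairwise_matrix()`);
* **anchors** — k-means clustering of ground-truth shapes under `1 − IOU`
  distance, anchor quality diagnostics, scale-group assignment, and the
  published 9-anchor platelet prior set as a constant
  (`kmeans_anchors()`, `mean_best_iou()`, `default_platelet_anchors()`);
* **data** — Pascal VOC XML annotation I/O, seeded dataset splitting with
  the reference 296/33/83-of-412 proportions, aspect-preserving letterbox
  preprocessing (`read_voc()`, `write_voc()`, `split_dataset()`,
  `letterbox()`);
* **synthetic smears** — a deterministic generator of stained-smear-like
  images (pale background, unlabelled erythrocyte distractors, small
  darker-stained platelet blobs with tight VOC boxes) so every stage is
  testable offline (`smear_config()`, `generate_dataset()`);
* **model** — a Darknet-53-style backbone with either the baseline
  13/26/52 multiscale head or the small-target **improved** variant that
  drops the 13×13 head and adds a 104×104 one (heads at strides 16/8/4), and
  a `width_mult` channel multiplier for desk-scale experiments
  (`detector_config()`, `build_detector()`);
* **training** — match-parameter target assignment, a `1 − CIOU` box loss
  with exact analytic gradients, balanced objectness BCE, the published
  learning-rate recipe (0.001 → 0.0001 at epoch 50, ×0.92 per epoch,
  batch 4), Adam, deterministic seeding (`train_detector()`, `lr_at()`);
* **inference & evaluation** — YOLO decode, greedy NMS (IOU 0.45),
  confidence threshold 0.25, and VOC-style precision / recall / F1 /
  uninterpolated AP with threshold sweeps (`detect()`, `nms()`,
  `evaluate_records()`, `threshold_sweep()`).

Everything — the conv/batchnorm layers, backpropagation, the optimiser — is
built in R on top of two small C++ kernels (im2col/col2im) and BLAS matrix
multiplication. No Python, no GPU, no deep-learning framework.

## Worked example

A reduced-scale version of the full pipeline — generate synthetic smears,
cluster anchors on the training boxes, train a width-0.125 improved-variant
detector at input 160, and evaluate on held-out images:

```r
library(plateletdetect)

res <- run_demo("demo_run", seed = 7)   # 120 images, 20 epochs, ~4 min on 1 CPU
#> epoch   1 lr 1.00e-03 loss 8.7247 (box 0.7872 obj 4.1183 cls 0.6706) val AP -
#> ...
#> epoch  20 lr 2.05e-05 loss 1.9923 (box 0.2549 obj 0.7003 cls 0.0174) val AP 0.481
#> TP 100  FP 687  FN 8  (TN: undefined for detection)
#> precision 0.1271  recall 0.9259  F1 0.2235  AP 0.4869
```

Reading the report: of the 108 platelets in the 24 held-out images the model
finds 100 (recall 0.93); at the 0.25 confidence threshold it also emits 687
spurious boxes (precision 0.13 — the demo is deliberately small, and
precision is the last thing to converge), and the area under the ranked
precision–recall path (uninterpolated AP, the headline detection metric) is
0.49. The acceptance suite runs the benchmark-scale version (150 training
images, 20 epochs, ~7 min) and requires AP ≥ 0.5; it reaches ≈0.7.

The same pipeline as a shell session:

```sh
Rscript inst/cli/plateletdetect generate --out data --n 412 --seed 1
Rscript inst/cli/plateletdetect cluster-anchors --annotations data/annotations --k 9 --seed 1 --out anchors.txt
Rscript inst/cli/plateletdetect train --data data --out run --epochs 100 --seed 1
Rscript inst/cli/plateletdetect detect --checkpoint run/best.ckpt --image data/images/smear_0001.ppm --conf 0.25 --nms-iou 0.45
Rscript inst/cli/plateletdetect evaluate --checkpoint run/best.ckpt --data data --split test --eval-iou 0.5
```

Formula-level building blocks:

```r
iou(box(0, 0, 10, 10), box(0, 0, 10, 10))   # 1: identical boxes
iou(box(0, 0, 1, 1), box(5, 5, 6, 6))       # 0: disjoint interiors
match_parameter(box(0, 0, 8, 8), box(0, 0, 8, 8))  # 2: CIOU + IOU at identity
f1(p = 0.8531, r = 0.8686)                  # 0.8608: harmonic mean
```

## Scope

The original platelet dataset is private and full-scale training is
GPU-sized, so published absolute AP values on real smears are out of scope;
the synthetic benchmark validates the implementation end to end instead. See
`vignettes/platelet-detection-methods.Rmd` for the model, the training
recipe, every numerical convention, and known limitations.
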