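---
title: "Stacked meta-regression for bounding-box ensembles: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stacked meta-regression for bounding-box ensembles: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stackbox)
```

## The problem

Several object detectors run on the same images rarely agree: each produces
boxes with its own systematic localization habits — one tends to shift boxes,
another inflates them, a third compresses coordinates toward the image
origin. Classical fusion rules (NMS and its relatives) *select* or *average*
among the candidate boxes, so the fused box can never be better located than
a (weighted) combination of its inputs. In medical applications such as
polyp detection during colonoscopy, localization quality matters: a box that
covers half the lesion is counted as a miss at strict IoU thresholds.

`stackbox` implements a stacking alternative: treat the base detectors'
boxes as *features* and learn, per coordinate, a regression from the
detectors' outputs onto the true coordinate. Because each detector's error
is largely systematic, a level-1 model can invert it, producing boxes more
accurate than any base detector — and than any weighted average of them.

## The stacking model

Let the roster contain $M \ge 2$ base learners, and write a box as
$(x_{\min}, y_{\min}, x_{\max}, y_{\max})$ in continuous pixel coordinates
(origin top-left, width $= x_{\max} - x_{\min}$ exactly).

**Training.** For each ground truth $g$ and each model $m$ independently,
the same-image same-class detection of $m$ with the highest IoU against $g$
is selected, provided that IoU exceeds `minIou` (default 0, i.e. any
overlap counts). Matching is non-exclusive: one detection may serve several
ground truths, mirroring the per-ground-truth argmax construction. A ground
truth matched by no model is discarded. In the remaining rows, an empty
slot is filled with a copy of the row's highest-IoU match regardless of its
source model; ties go to the earlier roster model, so the procedure is
deterministic. Four datasets are then built, one per coordinate: the $M$
predictor columns are the slot boxes' values of that coordinate (roster
order), the target is the ground truth's value, and one regressor is fitted
per coordinate. There is deliberately no joint multi-output model: the four
coordinates are regressed independently.

**Inference.** With no ground truth available, every model's predictions
serve as pseudo-ground-truths in turn: for each anchor detection the
best-IoU detection of each *other* model is matched; the anchor fills its
own model's slot, so rows have the same $M$-column design as in training.
Anchors supported by no other model are dropped — this is the mechanism by
which isolated false positives disappear. Missing slots are imputed exactly
as in training. Because mutually matching anchors generate identical rows,
duplicates (exact equality of the full $4M$-coordinate tuple, per image and
class) are collapsed to their first occurrence; equality is exact rather
than tolerance-based since duplicates arise by copying the very same
detections. Each surviving row is pushed through the four regressors to
give one refined box, and a final greedy NMS at IoU 0.5 removes redundant
refined boxes, keeping the most confident.

**Confidence of a stacked box.** The meta-regression predicts coordinates
only, yet the final NMS and the AP metrics need a score. We assign the mean
of the row's slot confidences (imputed slots included), with the maximum as
an option (`confMode = "max"`). The mean mirrors how weighted boxes fusion
treats confidence and behaved indistinguishably from the maximum in our
synthetic experiments.

**Meta-regressor backends.** Ordinary least squares (`"lr"`) is the default
and the reference: it is closed-form (QR), deterministic, and exactly
inverts affine coordinate distortions. Random forest (`"rf"`), and two
gradient-boosting configurations (`"gb"`, `"xgb"`) are available through a
seeded backend registry; they are useful when detector errors are
non-linear in the coordinates but need far more match rows to compete with
least squares. An adaptive-boosting backend is not shipped; the registry
accepts additional backends without changes elsewhere.

## Fusion baselines

Four classical rules, in six variants, are implemented for comparison and
as the final suppression step; all operate independently per image and per
class, with a stable tie-break (confidence descending, then roster order,
then input order):

* **NMS** — greedy selection by score; boxes overlapping a kept box with
  IoU above `iouThreshold` (default 0.5) are removed; survivors unchanged.
* **Soft-NMS** — instead of removal, overlapping scores decay by
  $s\,e^{-\mathrm{IoU}^2/\sigma}$ (Gaussian, $\sigma = 0.5$) or by
  $s\,(1-\mathrm{IoU})$ when IoU exceeds the threshold (linear); scores
  below `softScoreThreshold` (0.001) are dropped. The defaults follow the
  conventions established for this rescoring family.
* **NMW** — clusters are seeded greedily by score; fused coordinates are
  the member average weighted by $s_i \cdot \mathrm{IoU}(b_i,
  \text{seed})$; the seed's confidence is kept unchanged.
* **WBF** — members join the cluster whose *running fused box* they overlap
  best; fused coordinates are confidence-weighted means; fused confidence
  is the member mean (or maximum, `wbf-max`), rescaled by the fraction of
  roster models contributing to the cluster (`wbfRescale = TRUE` by
  default, matching the reference algorithm). Per-model weights default to
  1; nothing suggests unequal weights improve the packaged scenarios.

## Evaluation metrics

`evaluateDetections()` reports the ten headline quantities used in
detector comparisons: AP averaged over IoU thresholds $0.50{:}0.05{:}0.95$,
AP at 0.50 and 0.75, AP restricted to medium ($32^2 \le$ area $< 96^2$
px$^2$) and large ($\ge 96^2$) ground truths, AR at 1 and 10 detections
per image, bucketed AR (at 100 detections per image, the COCO default,
configurable), and class-averaged mAP at IoU 0.50. Precision is
interpolated at 101 recall points ($0, 0.01, \ldots, 1$) as the maximum
precision at any recall at or above the grid point. Evaluation matching is
greedy: detections in decreasing confidence claim the unmatched ground
truth with the highest IoU at or above the threshold, ties resolved by
IoU then first index. Size buckets are computed on ground-truth area;
a detection matched to an out-of-bucket ground truth is ignored rather
than counted as a false positive, and an unmatched detection whose own
area falls outside the bucket is ignored likewise — so size-restricted
metrics never punish correct detections of the other bucket. A bucket with
no ground truths yields `NA`, reported as absent rather than zero.

## The synthetic scenario generator

The packaged scenarios replace GPU-trained detectors with simulated base
learners that have the statistical structure stacking exploits. Images are
$640 \times 640$ px (the working resolution of the motivating colonoscopy
data); each image holds uniform $1$–$3$ ground-truth boxes with log-uniform
areas between $40^2$ and $200^2$ px$^2$ (spanning the medium and large
buckets) and aspect ratios uniform in $[0.6, 1.6]$. A simulated learner is
a `NoiseProfile`: per-coordinate affine map $c \mapsto a_k c + b_k$,
Gaussian jitter, a miss rate, a Poisson false-positive stream (false boxes
share the ground-truth size distribution, so overlap with real objects is
possible but not guaranteed), and Beta-distributed confidences with a
higher mean for true detections (shape $(8,2)$, mean $0.8$) than for false
positives (shape $(2,6)$, mean $0.25$). Sampling uses named seed
substreams, so adding or editing one model never perturbs the ground
truths or the other models' draws.

Three presets are shipped. `perfect` (200 images) has zero noise and is
used for idempotence checks. `bias` (500 images; jitter 2 px, miss rate
0.1, 0.5 false positives per image) gives the three learners distinct,
non-cancelling affine distortions — a diagonal shift ($1.02c + 8$), a
horizontal stretch ($1.04c - 5$ in $x$, $+14$ in $y$) and a dilation
($1.01c$ with $\mp 12$/$\pm 12$ px on the min/max corners). The
magnitudes are calibrated so each simulated learner sits in the operating
regime typical of real single-stage polyp detectors: most detections clear
IoU 0.5 on large lesions but almost none clear IoU 0.75 (AP@.50 roughly
0.3–0.6, AP@.75 below 0.1). In that regime a confidence-weighted average
(WBF) stays biased — the three affine maps do not cancel — while
least-squares stacking inverts each map up to jitter, which is exactly the
contrast the package exists to demonstrate. `hard` keeps the same maps
with jitter 6 px, miss rate 0.25, and 1 false positive per image.

What the simulator does *not* model: correlated misses between detectors,
confidence scores that covary with localization quality, non-affine or
object-size-dependent distortions, crowded scenes with overlapping ground
truths, and any appearance information. Tests passing on these scenarios
therefore demonstrate the correctness of the machinery and the claimed
qualitative ordering under systematic bias, not performance on real
colonoscopy data.

## Numerical and degenerate-input choices

* Equal-confidence ties everywhere resolve by roster order then input
  order, so every routine is deterministic given its inputs.
* Zero-area boxes are rejected at construction/read time with a logged
  count; IoU against them is undefined and they corrupt matching.
* Predicted boxes with $\min \ge \max$ on either axis are dropped (with a
  message), not repaired: they occur only when a regressor extrapolates
  far outside its training support, and repairing would fabricate geometry.
* Out-of-image coordinates are clamped (`policy = "clip"`); boxes left
  without positive extent are removed.
* Least squares uses a QR decomposition; aliased (collinear) predictor
  columns receive zero coefficients rather than failing, which arises
  naturally when two simulated learners coincide.
* Image-disjoint cross-validation folds are assigned by shuffling unique
  image identifiers under the run seed; box counts per fold may differ,
  image counts differ by at most one.

## Problem sizes used by the shipped checks

Unit tests run on scenarios of 10–50 images; the oracle equivalences use
100–500 random instances of at most 8 boxes. The acceptance-style checks
use the presets at their default sizes: 200 images for the perfect
pipeline, 500 images (400 training / 100 held-out) per seed for the
bias-correction comparison across five seeds, and a fivefold
cross-validation on the 500-image bias preset. These sizes give the
comparison statistical headroom (about 200 held-out ground truths per
seed) while keeping a full run in the order of a minute on one CPU.

## Known limitations

* The method refines *where* boxes are, not *whether* they exist: recall is
  capped by the union of base-learner detections, and an object found by
  only one model is dropped at test time by the support rule. On the bias
  preset this costs a few recall points relative to WBF's near-perfect
  recall, and the package makes no attempt to recover such singletons.
* Confidence of stacked boxes is a heuristic (slot mean); no calibration is
  attempted.
* Multi-class data are handled by running the pipeline independently per
  class, which is correct but unoptimised for many classes.
* The least-squares backend assumes detector errors are affine in the
  coordinates; markedly non-linear distortions require the tree backends
  and correspondingly more training rows.
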