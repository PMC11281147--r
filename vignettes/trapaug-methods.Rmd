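---
title: "trapaug methods: conventions, parameters, and numerical choices"
author: "Package Author"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{trapaug methods: conventions, parameters, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trapaug)
```

# Scope

`trapaug` implements label-preserving data augmentation for object
detection on sticky-trap insect images, deterministic dataset
enrichment, detection evaluation (mAP), and a synthetic image generator
with exact ground truth. This vignette records every convention and
numerical decision the implementation relies on, so results can be
reproduced or re-implemented independently.

# Data model

## Images

An image is an integer-valued `double` array `[height, width, 3]` with
intensities in 0..255. Pixel coordinates are continuous with the origin
at the top-left corner; pixel `(i, j)` (row, column, 1-based) occupies
the unit square whose center is `(j - 0.5, i - 0.5)` in `(x, y)`.

## Annotations

Boxes follow the YOLO text format: `class_id cx cy w h`, all four
geometric fields normalized by image width/height so the image is the
unit square. Detections carry a sixth field, `confidence` in [0, 1].
Serialization (`writeYoloAnnotation`) uses six decimal places; the
round trip through text is therefore exact to about `1e-6` in
normalized units, which is far below a pixel at any realistic
resolution.

`AnnotatedImage` bundles an image, its box table, an identifier, and a
`provenance` tag naming the operator that produced it (`original`,
`gamma`, `brightness_contrast`, `noise`, `translation`, `rotation`,
`mosaic`, `modified_mosaic`). Validity checks run at construction:
dimensions, intensity range, integer-valuedness, and box geometry.

## Rounding

All intensity quantization uses round-half-away-from-zero,
`floor(x + 0.5)`, applied after clipping to the representable range.
This matches the rounding used by mainstream image libraries and makes
the scalar definitions below exact specifications, not approximations.

# Photometric operators

Photometric transforms change intensities only; the box table passes
through untouched.

* **Gamma**: `out = round(255 * clip01(gain * (v / 255)^gamma))`,
  default `gain = 1`. `gamma < 1` brightens, `gamma > 1` darkens.
* **Brightness–contrast**: `out = round(clip(alpha * v + beta, 0, 255))`.
* **Multiplicative Gaussian noise**: `out = round(clip(v * n, 0, 255))`
  with `n ~ N(mean, sd^2)`, defaults `mean = 1`, `sd = 0.2`. One draw
  is made per *pixel* and shared across the three channels
  (`perChannel = FALSE` default), so noise perturbs brightness without
  decorrelating hue. Sticky-trap channels have similar intensity
  distributions (see `channelHistograms`), which is what justifies a
  single shared mapping per pixel.

`samplePhotometricParams()` draws `gamma ~ U(0.2, 3)`,
`alpha ~ U(0.5, 2)`, `beta ~ U(-50, 50)` — ranges wide enough to cover
realistic illumination variation over a trap while keeping most of the
dynamic range unclipped.

# Geometric operators

## Conventions

Rotation angles are in degrees, counter-clockwise positive *in the
displayed image* (the y-down raster frame), about the canvas center
`(W/2, H/2)`. The forward map of a point on the unit square is, at 90°,
`(x, y) -> (y, 1 - x)`. Resampling is inverse-mapping bilinear
interpolation; destination samples falling outside the source get the
constant fill `(114, 114, 114)`, the conventional neutral-gray padding
of YOLO-family pipelines. Translation is by an integer pixel shift
(`round(dx * W)`, `round(dy * H)`), so translated pixels are copied
exactly, never interpolated.

## Box mapping: AABB-then-clip

A transformed annotation is computed by mapping the four box corners
with the exact forward transform, taking their axis-aligned bounding
box (AABB), and clipping that AABB to the canvas. Rotating a box by
45° therefore grows its annotation by a factor of `sqrt(2)` per side:
the AABB is a *conservative cover* of the rotated object, which is the
standard labeling convention for rotation augmentation (the object is
guaranteed inside its box; the box may include background). The
alternative — tightly bounding the clipped rotated polygon — would
produce tighter boxes near the border but is not what detector training
pipelines expect.

## Degenerate-box rule

After clipping, a box is dropped if its visible area is less than 25 %
of its pre-clip area **or** either side is below 2 pixels. Both
thresholds are exposed (`minAreaFrac`, `minPixels`). The area test
includes a `1e-12` slack so boxes exactly at the threshold (for
example, a centered box split into four exact quarters by a mosaic) are
kept rather than lost to floating-point noise.

`sampleGeometricParams()` draws `dx, dy ~ U(-0.2, 0.2)` (shifts up to
20 % of the canvas) and `theta ~ U(-90, 90)`.

# Mosaic

`makeMosaic` composes four annotated images into one `S × S` canvas
(`S` defaults to the largest source dimension). Each source is rescaled
to `S × S`, a center `(cx, cy)` is drawn uniformly from
`0.5 ± maxOffset` per axis (default `maxOffset = 0.3`; values ≥ 0.5 are
rejected), and the integer split point is `round(c * S)` clamped to
keep every quadrant at least 1 px. Quadrant `q` of the canvas is filled
from region `q` of rescaled source `q` (`cropAnchor = "corner"`), so a
source's boxes shift by `(rect_origin - source_window) / S` — zero for
the corner anchor — and are then clipped to their quadrant with the
degenerate-box rule above.

`makeModifiedMosaic` additionally applies, to each rescaled sub-image
*before* composition and independently per quadrant,
brightness–contrast with probability `0.8` and multiplicative noise
with probability `0.3` (parameters re-drawn per sub-image from the
samplers above). The RNG consumption order is fixed — center, crop
windows, then per-quadrant decisions — and with both probabilities set
to zero the output is bit-identical to `makeMosaic` under the same
seed, which is also how the implementation is tested.

# Enrichment

`EnrichmentPlan(methods, multiple, seed)` declares `k` methods applied
`m` times each; `enrichDataset` turns `n` originals into
`n * (1 + k * m)` images (originals retained by default). At the
reference problem size of 330 annotated images, a two-method plan
yields 990 images and a three-method plan 1320.

Reproducibility is per-image, not per-run: each augmented image is
produced under `set.seed(deriveSeed(master, method, pass, image))`,
where `deriveSeed` is a Lehmer-style mix modulo `2^31 - 1`. Adding a
method or reordering the dataset therefore never changes the images
produced for unaffected `(method, pass, image)` triples. Mosaic methods
consume a seeded shuffle of the dataset four sources at a time, with
duplicates across group boundaries resolved deterministically, so every
original appears as a mosaic source equally often.

`writeEnrichedDataset` writes `images/*.png`, `labels/*.txt`, and a
JSON manifest (ids, provenance, box counts); everything is plain text
or PNG and replays byte-identically from the same master seed.

# Detection evaluation

Matching is greedy in descending confidence (stable order on ties).
Each detection is assigned the *unmatched* same-class ground-truth box
of highest IoU among those with IoU > 0, and that box is consumed by
the assignment regardless of the IoU threshold `t`; the detection
counts as a true positive only if the assigned IoU ≥ `t`. Making the
assignment threshold-independent keeps average precision monotonically
non-increasing in `t`, a property the test suite asserts; letting the
threshold gate the assignment itself can make a stricter threshold
yield a *higher* AP through different pairings.

Precision–recall curves accumulate TP/FP in confidence order; AP is
the area under the precision envelope (`rev(cummax(rev(precision)))`),
with all-points interpolation by default and 11-point / 101-point
variants available. `evaluateDetections` sweeps IoU thresholds 0.50 to
0.95 in steps of 0.05, computes per-class AP (classes taken from the
ground truth), and macro-averages into mAP@50 and mAP@50–95.

# Synthetic trap images

`generateTrapImage` emulates the photometric structure of a yellow
sticky trap photographed from above:

* background: per-image base level `U(190, 225)`, a linear gradient of
  span 35 across the canvas (uneven illumination), Gaussian texture of
  sd 6, and a warm channel tint `(1.00, 0.97, 0.90)`;
* insects: dark filled ellipses, axes `U(4, 14)` px and free
  orientation, intensity `U(25, 80)` plus `N(0, 6)` speckle;
* placement: rejection sampling keeps bounding boxes non-overlapping
  with 2 px padding (up to 1000 attempts, then an informative error);
* ground truth: the tight AABB of each insect's *rendered* mask, so
  annotations are exact by construction.

The generator is a controlled stand-in, not a photorealistic model: it
reproduces the aspects the operators and the evaluator are sensitive to
(bright background vs. dark compact objects, illumination gradients,
channel correlation, box tightness) and deliberately omits occlusion,
insect appendages, specular glare, and multiple classes.
`generateDetections` simulates a detector on exact ground truth with a
miss probability, Poisson-distributed spurious boxes, and Gaussian
center/size jitter — enough to drive the evaluator across the full
quality range with known expectations (perfect input must give
mAP = 1; growing jitter must not increase mAP).

# Problem sizes and limitations

The package's reference experiment size — 330 annotated originals
enriched to 990 (pair strategy) or 1320 (triple strategy) — reflects
the scale at which sticky-trap datasets are typically collected, and is
the size exercised by the test suite and the acceptance script.

Known limitations:

* Rotation annotations are conservative AABBs; for elongated objects at
  45° they substantially over-cover, and boxes whose rotated AABB
  leaves the canvas are clipped rather than re-tightened to the visible
  polygon.
* The resampler is plain bilinear; no anti-aliasing filter is applied
  when mosaic rescaling shrinks a source by a large factor.
* Evaluation assumes single-label boxes and class-exact matching; there
  is no support for crowd/ignore regions.
* The synthetic generator models one insect class and clean traps; it
  is a test harness for the toolchain, not a substitute for real
  training data.

# Session info

```{r}
sessionInfo()
```
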