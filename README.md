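# trapaug

Data augmentation, dataset enrichment, and detection evaluation for
sticky-trap insect monitoring images with YOLO-format annotations.

## The problem

Automated pest monitoring places cameras over yellow sticky traps and
trains object detectors to count the captured insects. Annotated trap
images are expensive to collect, so practical training sets are small —
on the order of a few hundred images. Data augmentation expands such a
set by applying label-preserving transforms to each image, and the
choice and combination of transforms measurably changes detector
accuracy.

`trapaug` implements that workflow as composable, fully reproducible R
operators:

* **Photometric transforms** that perturb intensities and leave boxes
  untouched: gamma correction
  `out = round(255 · clip(gain · (v/255)^γ))`, linear
  brightness–contrast `out = round(clip(α·v + β, 0, 255))`, and
  multiplicative Gaussian noise `v · n` with `n ~ N(1, 0.2²)` drawn once
  per pixel and shared across channels.
* **Geometric transforms** that move both pixels and boxes: integer
  pixel translation and rotation about the canvas center (CCW-positive
  in the y-down image frame, bilinear resampling, gray fill
  `(114,114,114)`). A transformed box is the axis-aligned bounding box
  of its mapped corners, clipped to the canvas; boxes that lose more
  than 75 % of their area or shrink below 2 px on a side are dropped.
* **Mosaic augmentation**: four annotated images rescaled to a common
  square and composed around a randomly placed center (offset up to
  ±30 % of the canvas from its middle), with all boxes remapped and
  clipped per quadrant. A *modified* mosaic additionally applies
  brightness–contrast with probability 0.8 and multiplicative noise
  with probability 0.3 to each sub-image, independently, before
  composition.
* **Dataset enrichment**: a declarative `EnrichmentPlan` (methods × a
  per-method multiple) expands `n` originals into `n · (1 + k · m)`
  images with deterministic per-image sub-seeding, so an enriched
  dataset replays byte-for-byte from one master seed. Two reference
  strategies: a pair of methods at multiple 1 turns 330 images into
  990; a triple turns 330 into 1320.
* **Detection evaluation**: IoU, greedy confidence-ordered matching,
  precision–recall curves, and average precision (all-points, 11-point,
  or 101-point interpolation), aggregated to mAP@50 and mAP@50–95 over
  the IoU sweep 0.50, 0.55, …, 0.95.
* **Synthetic trap images** with exact ground truth: bright paper-like
  backgrounds (gradient + texture + warm tint) carrying dark,
  non-overlapping elliptical insects, plus a configurable simulated
  detector (`pMiss`, Poisson spurious boxes, center/size jitter) for
  exercising the evaluator end to end.

Annotations use the YOLO text format (`class cx cy w h`, normalized to
the unit square; detections carry a sixth confidence field) and the
standard `images/` + `labels/` directory layout, so datasets written by
`trapaug` drop directly into common detector training pipelines.

## Worked example

```r
library(trapaug)

## six synthetic trap images with exact ground truth
cfg  <- SynthConfig(imageSize = 128, nInsects = c(3L, 8L))
imgs <- generateSyntheticImages(6, cfg, seed = 42)
imgs[[1]]
#> AnnotatedImage 'synth_0001' [original]
#>   raster: 128 x 128 x 3, intensities 15..255
#>   boxes:  7 (classes: 0)

## enrich with the photometric pair strategy: n -> n * (1 + 2)
plan <- EnrichmentPlan(c("gamma", "brightness_contrast"),
                       multiple = 1, seed = 42)
out <- enrichDataset(imgs, plan)
length(out)
#> [1] 18
table(vapply(out, provenance, character(1)))
#> brightness_contrast               gamma            original
#>                   6                   6                   6

## evaluate a simulated, imperfect detector against the ground truth
gt <- lapply(imgs, boxes)
names(gt) <- vapply(imgs, imageId, character(1))
set.seed(42)
det <- lapply(gt, function(g)
  generateDetections(g, pMiss = 0.1, pSpurious = 0.5, jitterSd = 0.04))
evaluateDetections(det, gt)
#> EvalResult
#>   classes:   1
#>   IoU sweep: 0.50 0.55 0.60 0.65 0.70 0.75 0.80 0.85 0.90 0.95
#>   mAP50:     0.9444
#>   mAP50-95:  0.6768
```

Datasets round-trip through disk with `writeEnrichedDataset()` /
`readDataset()` (PNG images, YOLO labels, JSON manifest), and
`generateSyntheticDataset()` writes a ready-to-train synthetic set in
one call. A thin command-line front end with `synth`, `augment`, and
`evaluate` subcommands is installed at
`system.file("scripts", "trapaug.R", package = "trapaug")`.

## License

MIT (see `LICENSE`).
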