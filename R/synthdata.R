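## Synthetic sticky-trap imagery: a bright, slightly warm paper surface
## with a linear illumination gradient and fine texture, carrying small
## dark elliptical "insects" at known, non-overlapping positions. The
## generator exists so augmentation and evaluation pipelines can be
## exercised end-to-end with exact ground truth and no field data.

## fixed warm tint of the paper surface (R, G, B multipliers)
.PAPER_TINT <- c(1.00, 0.97, 0.90)

#' Generate one synthetic trap image with exact ground truth
#'
#' Draws the background level, illumination gradient direction, insect
#' count, and each insect's position, semi-axes, orientation and darkness
#' from the current R random stream (seed with [set.seed()] for
#' reproducibility). Each insect is a filled ellipse; its ground-truth box
#' is the tight axis-aligned bound of the rendered pixels. Insects are
#' placed by rejection sampling so their boxes never overlap.
#'
#' @param cfg a [SynthConfig-class].
#' @param id identifier for the image.
#' @param nInsects override the config's insect-count range with a fixed
#'   count (optional).
#' @return an [AnnotatedImage-class] with provenance `"original"`.
#' @export
generateTrapImage <- function(cfg = SynthConfig(), id = "synth",
                              nInsects = NULL) {
  stopifnot(is(cfg, "SynthConfig"))
  validObject(cfg)
  S <- cfg@imageSize
  ## paper background: base level + directional linear ramp + shared texture
  base <- runif(1, cfg@backgroundLevel[1L], cfg@backgroundLevel[2L])
  phi <- runif(1, 0, 2 * pi)
  xg <- matrix(rep((seq_len(S) - 0.5) / S - 0.5, each = S), nrow = S)
  yg <- matrix(rep((seq_len(S) - 0.5) / S - 0.5, times = S), nrow = S)
  ramp <- (xg * cos(phi) + yg * sin(phi)) * cfg@gradientStrength
  texture <- matrix(rnorm(S * S, 0, cfg@textureStd), nrow = S)
  lum <- base + ramp + texture
  img <- array(0, dim = c(S, S, 3L))
  for (ch in 1:3) img[, , ch] <- lum * .PAPER_TINT[ch]

  n <- if (is.null(nInsects))
    cfg@nInsects[1L] +
      sample.int(cfg@nInsects[2L] - cfg@nInsects[1L] + 1L, 1L) - 1L
  else as.integer(nInsects)
  placed <- matrix(numeric(0), ncol = 4L)  # x0, y0, x1, y1 (pixels)
  rows <- vector("list", n)
  i <- 0L
  attempts <- 0L
  while (i < n) {
    attempts <- attempts + 1L
    if (attempts > 1000L)
      stop("could not place ", n, " non-overlapping insects in 1000 ",
           "attempts; reduce the count or the insect size", call. = FALSE)
    a <- runif(1, cfg@insectAxes[1L], cfg@insectAxes[2L])
    b <- runif(1, cfg@insectAxes[1L], cfg@insectAxes[2L])
    th <- runif(1, 0, pi)
    ## half-extents of the rotated ellipse's tight AABB
    hx <- sqrt((a * cos(th))^2 + (b * sin(th))^2)
    hy <- sqrt((a * sin(th))^2 + (b * cos(th))^2)
    cx <- runif(1, hx + 1, S - hx - 1)
    cy <- runif(1, hy + 1, S - hy - 1)
    box <- c(cx - hx, cy - hy, cx + hx, cy + hy)
    if (nrow(placed)) {
      pad <- 2
      clash <- placed[, 1L] < box[3L] + pad & placed[, 3L] > box[1L] - pad &
               placed[, 2L] < box[4L] + pad & placed[, 4L] > box[2L] - pad
      if (any(clash)) next
    }
    ## render: pixel centers inside the rotated ellipse
    jr <- max(1L, floor(box[1L])):min(S, ceiling(box[3L]))
    ir <- max(1L, floor(box[2L])):min(S, ceiling(box[4L]))
    px <- rep(jr - 0.5, each = length(ir)) - cx
    py <- rep(ir - 0.5, times = length(jr)) - cy
    u <- (px * cos(th) + py * sin(th)) / a
    v <- (-px * sin(th) + py * cos(th)) / b
    inside <- matrix(u^2 + v^2 <= 1, nrow = length(ir))
    if (!any(inside)) next
    dark <- runif(1, 25, 80)
    bodyTexture <- rnorm(sum(inside), 0, 6)
    for (ch in 1:3) {
      sl <- img[ir, jr, ch]
      sl[inside] <- dark + bodyTexture
      img[ir, jr, ch] <- sl
    }
    ## tight box from the rendered mask
    jin <- jr[colSums(inside) > 0]
    iin <- ir[rowSums(inside) > 0]
    rect <- data.frame(x_min = min(jin) - 1, y_min = min(iin) - 1,
                       x_max = max(jin), y_max = max(iin))
    i <- i + 1L
    placed <- rbind(placed, box)
    rows[[i]] <- pixelToBox(rect, S, S, class_id = 0L)
  }
  bx <- if (n > 0L) do.call(rbind, rows) else yoloBoxes()
  rownames(bx) <- NULL
  img <- .roundHalfUp(.clip0255(img))
  AnnotatedImage(img, boxes = bx, id = id, provenance = "original",
                 meta = list(generator = "synthetic_trap"))
}

#' Simulate a detector's output for known ground truth
#'
#' Produces a controlled detection set: each ground-truth box is missed
#' with probability `pMiss`, otherwise emitted with Gaussian jitter on its
#' center and size (`jitterSd` as a fraction of the box dimensions) and a
#' confidence drawn from `U(0.6, 1)`; additionally, `Poisson(pSpurious)`
#' false boxes appear at random positions with confidences in
#' `U(0.1, 0.6)`. Uses the current R random stream.
#'
#' @param groundTruth a box data.frame.
#' @param pMiss per-box miss probability.
#' @param pSpurious expected number of false detections per image.
#' @param jitterSd perturbation standard deviation, as a fraction of box
#'   width/height.
#' @return a detection data.frame.
#' @export
generateDetections <- function(groundTruth, pMiss = 0, pSpurious = 0,
                               jitterSd = 0) {
  validateBoxes(groundTruth)
  stopifnot(pMiss >= 0, pMiss <= 1, pSpurious >= 0, jitterSd >= 0)
  rows <- list()
  for (i in seq_len(nrow(groundTruth))) {
    if (runif(1) < pMiss) next
    g <- groundTruth[i, ]
    w <- max(g$w * (1 + rnorm(1, 0, jitterSd)), 1e-4)
    h <- max(g$h * (1 + rnorm(1, 0, jitterSd)), 1e-4)
    cx <- g$cx + rnorm(1, 0, jitterSd * g$w)
    cy <- g$cy + rnorm(1, 0, jitterSd * g$h)
    ## keep the jittered box inside the unit square
    w <- min(w, 1); h <- min(h, 1)
    cx <- min(max(cx, w / 2), 1 - w / 2)
    cy <- min(max(cy, h / 2), 1 - h / 2)
    rows[[length(rows) + 1L]] <-
      data.frame(class_id = g$class_id, cx = cx, cy = cy, w = w, h = h,
                 confidence = runif(1, 0.6, 1.0))
  }
  nFp <- rpois(1, pSpurious)
  for (k in seq_len(nFp)) {
    w <- runif(1, 0.02, 0.08); h <- runif(1, 0.02, 0.08)
    rows[[length(rows) + 1L]] <-
      data.frame(class_id = 0L, cx = runif(1, w / 2, 1 - w / 2),
                 cy = runif(1, h / 2, 1 - h / 2), w = w, h = h,
                 confidence = runif(1, 0.1, 0.6))
  }
  if (length(rows) == 0L) return(yoloDetections())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a synthetic dataset on disk
#'
#' Writes `nImages` trap images in the standard `images/` + `labels/`
#' layout with a JSON manifest. Per-image seeds are derived from the master
#' seed, so regeneration with the same arguments is byte-identical.
#'
#' @param nImages number of images (at least 1).
#' @param cfg a [SynthConfig-class].
#' @param outDir output directory.
#' @param seed master seed.
#' @return invisibly, the manifest as a list.
#' @export
generateSyntheticDataset <- function(nImages, cfg = SynthConfig(), outDir,
                                     seed = 1L) {
  if (nImages < 1L) stop("nImages must be at least 1", call. = FALSE)
  imgs <- generateSyntheticImages(nImages, cfg, seed = seed)
  writeEnrichedDataset(imgs, outDir,
                       extra = list(generator = "synthetic_trap",
                                    seed = seed,
                                    image_size = cfg@imageSize))
}

#' Generate a list of synthetic trap images in memory
#'
#' @inheritParams generateSyntheticDataset
#' @return list of [AnnotatedImage-class] objects with ids
#'   `synth_0001`, `synth_0002`, ...
#' @export
generateSyntheticImages <- function(nImages, cfg = SynthConfig(),
                                    seed = 1L) {
  lapply(seq_len(nImages), function(i) {
    set.seed(.deriveSeed(seed, 7L, i))
    generateTrapImage(cfg, id = sprintf("synth_%04d", i))
  })
}
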