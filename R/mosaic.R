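## Mosaic composition: one training image built from four sources, split
## by a randomly offset center point. Increases small-object density and
## per-image diversity, which is what makes it effective on trap images
## where each insect occupies a tiny fraction of the canvas.

#' Sample a mosaic center point
#'
#' Draws `cx, cy ~ U(0.5 - maxOffset, 0.5 + maxOffset)` independently:
#' the center may be offset by up to `maxOffset` of the merged image size
#' per axis (default 0.3).
#'
#' @param maxOffset maximum per-axis center offset, in `[0, 0.5)`.
#' @return numeric `c(cx, cy)`.
#' @export
sampleMosaicCenter <- function(maxOffset = 0.3) {
  if (!is.numeric(maxOffset) || maxOffset < 0 || maxOffset >= 0.5)
    stop("maxOffset must lie in [0, 0.5) (0.5 would empty a quadrant)",
         call. = FALSE)
  runif(2, 0.5 - maxOffset, 0.5 + maxOffset)
}

## Quadrant bookkeeping: integer split column xc / row yc gives rectangles
## TL = rows 1..yc, cols 1..xc; TR = rows 1..yc, cols xc+1..S; etc.
.quadrantRects <- function(S, xc, yc) {
  list(tl = c(1, 1, xc, yc), tr = c(xc + 1, 1, S, yc),
       bl = c(1, yc + 1, xc, S), br = c(xc + 1, yc + 1, S, S))
}

.composeMosaic <- function(rescaled, sources, S, center, cropAnchor,
                           minAreaFrac, provenance, meta) {
  xc <- min(max(round(center[1L] * S), 1L), S - 1L)
  yc <- min(max(round(center[2L] * S), 1L), S - 1L)
  quads <- .quadrantRects(S, xc, yc)
  out <- array(0, dim = c(S, S, 3L))
  allBoxes <- list()
  for (q in seq_along(quads)) {
    rect <- quads[[q]]
    qw <- rect[3L] - rect[1L] + 1L
    qh <- rect[4L] - rect[2L] + 1L
    if (cropAnchor == "corner") {
      sx0 <- rect[1L]; sy0 <- rect[2L]
    } else {
      sx0 <- 1L + floor(runif(1) * (S - qw + 1))
      sy0 <- 1L + floor(runif(1) * (S - qh + 1))
    }
    out[rect[2L]:rect[4L], rect[1L]:rect[3L], ] <-
      rescaled[[q]][sy0:(sy0 + qh - 1L), sx0:(sx0 + qw - 1L), , drop = FALSE]
    bx <- boxes(sources[[q]])
    if (nrow(bx)) {
      ## sources are rescaled uniformly, so normalized coordinates carry
      ## over; the crop shifts them by (dest - src) window origin.
      bx$cx <- bx$cx + (rect[1L] - sx0) / S
      bx$cy <- bx$cy + (rect[2L] - sy0) / S
      dst <- c((rect[1L] - 1L) / S, (rect[2L] - 1L) / S,
               rect[3L] / S, rect[4L] / S)
      bx <- .clipBoxesToRect(bx, dst, S, S, minAreaFrac = minAreaFrac)
      allBoxes[[q]] <- bx
    }
  }
  bx <- if (length(allBoxes)) do.call(rbind, allBoxes) else yoloBoxes()
  rownames(bx) <- NULL
  AnnotatedImage(out, boxes = bx, id = meta$id, provenance = provenance,
                 meta = meta[names(meta) != "id"])
}

#' Compose a mosaic from four annotated images
#'
#' The output canvas (`size` x `size`) is split into four quadrants by the
#' center point; each source is uniformly rescaled to the full canvas size
#' and quadrant q shows the same-corner-anchored crop of source q (the
#' top-left quadrant shows the first source's top-left region, and so on).
#' With `cropAnchor = "random"` each quadrant instead shows a uniformly
#' placed window of its rescaled source. Source boxes are mapped through
#' the rescale and crop, clipped to their quadrant, and dropped under the
#' usual visibility rule.
#'
#' @param sources list of exactly four [AnnotatedImage-class] objects
#'   (top-left, top-right, bottom-left, bottom-right).
#' @param center normalized mosaic center `c(cx, cy)`; `NULL` (default)
#'   samples it with [sampleMosaicCenter()].
#' @param size output canvas side in pixels; defaults to the largest
#'   dimension among the sources.
#' @param maxCenterOffset passed to [sampleMosaicCenter()] when `center`
#'   is `NULL` (default 0.3).
#' @param cropAnchor `"corner"` (default) or `"random"` crop window.
#' @param minAreaFrac visibility drop threshold (default 0.25).
#' @param id identifier for the composed image.
#' @return an `AnnotatedImage` with provenance `"mosaic"`.
#' @export
makeMosaic <- function(sources, center = NULL, size = NULL,
                       maxCenterOffset = 0.3,
                       cropAnchor = c("corner", "random"),
                       minAreaFrac = 0.25, id = "mosaic") {
  cropAnchor <- match.arg(cropAnchor)
  .checkMosaicSources(sources)
  if (is.null(size))
    size <- max(vapply(sources, function(s) max(dim(s)), numeric(1)))
  size <- as.integer(size)
  if (is.null(center)) center <- sampleMosaicCenter(maxCenterOffset)
  .checkCenter(center, maxCenterOffset)
  rescaled <- lapply(sources, function(s)
    .resizeArray(imageArray(s), size, size))
  .composeMosaic(rescaled, sources, size, center, cropAnchor, minAreaFrac,
                 "mosaic",
                 list(id = id, center = center,
                      sources = vapply(sources, imageId, character(1))))
}

#' Compose a modified mosaic with stochastic photometric sub-transforms
#'
#' Before composition, each of the four (rescaled) sub-images is
#' independently modified: with probability `pBrightnessContrast` a
#' brightness-contrast adjustment with freshly sampled parameters
#' (`alpha ~ U(0.5, 2)`, `beta ~ U(-50, 50)`) is applied, and with
#' probability `pNoise` multiplicative Gaussian noise (mean 1, sd 0.2).
#' The two decisions are independent Bernoulli draws, so both transforms
#' may hit the same sub-image. Composition then proceeds exactly as in
#' [makeMosaic()]. With both probabilities at 0 the result is bit-identical
#' to the plain mosaic under the same seed.
#'
#' @inheritParams makeMosaic
#' @param pBrightnessContrast probability of applying brightness-contrast
#'   to a sub-image (default 0.8).
#' @param pNoise probability of applying Gaussian noise (default 0.3).
#' @return an `AnnotatedImage` with provenance `"modified_mosaic"`.
#' @export
makeModifiedMosaic <- function(sources, center = NULL, size = NULL,
                               maxCenterOffset = 0.3,
                               pBrightnessContrast = 0.8, pNoise = 0.3,
                               cropAnchor = c("corner", "random"),
                               minAreaFrac = 0.25, id = "modified_mosaic") {
  cropAnchor <- match.arg(cropAnchor)
  .checkMosaicSources(sources)
  if (any(c(pBrightnessContrast, pNoise) < 0) ||
      any(c(pBrightnessContrast, pNoise) > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (is.null(size))
    size <- max(vapply(sources, function(s) max(dim(s)), numeric(1)))
  size <- as.integer(size)
  if (is.null(center)) center <- sampleMosaicCenter(maxCenterOffset)
  .checkCenter(center, maxCenterOffset)
  rescaled <- lapply(sources, function(s)
    .resizeArray(imageArray(s), size, size))
  applied <- vector("list", 4L)
  for (q in 1:4) {
    dec <- sampleSubimageTransforms(pBrightnessContrast, pNoise)
    a <- rescaled[[q]]
    if (dec$brightness_contrast)
      a <- .roundHalfUp(.clip0255(dec$alpha * a + dec$beta))
    if (dec$noise) {
      n <- array(rep(rnorm(size * size, 1, 0.2), 3L),
                 dim = c(size, size, 3L))
      a <- .roundHalfUp(.clip0255(a * n))
    }
    rescaled[[q]] <- a
    applied[[q]] <- dec
  }
  .composeMosaic(rescaled, sources, size, center, cropAnchor, minAreaFrac,
                 "modified_mosaic",
                 list(id = id, center = center,
                      sources = vapply(sources, imageId, character(1)),
                      subimage = applied))
}

#' Sample the per-sub-image transform decisions of the modified mosaic
#'
#' One independent Bernoulli draw per transform, plus the brightness-
#' contrast parameters when that transform fires. Exposed so the decision
#' process can be simulated without composing images.
#'
#' @param pBrightnessContrast,pNoise transform probabilities.
#' @return list with logicals `brightness_contrast`, `noise` and, when the
#'   former is `TRUE`, the sampled `alpha` and `beta`.
#' @export
sampleSubimageTransforms <- function(pBrightnessContrast = 0.8,
                                     pNoise = 0.3) {
  bc <- runif(1) < pBrightnessContrast
  dec <- list(brightness_contrast = bc, alpha = NULL, beta = NULL,
              noise = runif(1) < pNoise)
  if (bc) {
    dec$alpha <- runif(1, 0.5, 2.0)
    dec$beta <- runif(1, -50, 50)
  }
  dec
}

.checkMosaicSources <- function(sources) {
  if (!is.list(sources) || length(sources) != 4L)
    stop("mosaic needs exactly 4 source images", call. = FALSE)
  lapply(sources, .checkImage)
  invisible(TRUE)
}

.checkCenter <- function(center, maxOffset) {
  if (length(center) != 2L || any(abs(center - 0.5) > maxOffset + 1e-9) ||
      any(center <= 0) || any(center >= 1))
    stop("mosaic center must lie within the configured offset of (0.5, 0.5)",
         call. = FALSE)
  invisible(TRUE)
}
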