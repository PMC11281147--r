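## Internal numeric helpers shared across operators.

## Round half away from zero. All clipped intensities are non-negative, so
## floor(x + 0.5) implements the rule exactly and identically on every
## platform (unlike base round(), which rounds half to even).
.roundHalfUp <- function(x) floor(x + 0.5)

.clip01 <- function(x) pmin(pmax(x, 0), 1)

.clip0255 <- function(x) pmin(pmax(x, 0), 255)

## Deterministic sub-seed derivation: a Lehmer-style mix keeping every
## intermediate below 2^47 so double arithmetic is exact; result in
## [1, 2^31 - 2], safe for set.seed().
.deriveSeed <- function(master, ...) {
  m <- 2147483647
  s <- (abs(as.numeric(master)) %% m)
  for (v in c(...)) {
    s <- (s * 48271) %% m
    s <- (s + abs(as.numeric(v)) + 1) %% m
  }
  as.integer((s %% (m - 2)) + 1)
}

## Clip boxes to a rectangle (normalized coordinates) and apply the
## visibility drop rule: a box is kept only if its clipped area is at least
## `minAreaFrac` of its pre-clip area and both clipped sides measure at
## least `minPixels` in the target image.
.clipBoxesToRect <- function(boxes, rect = c(0, 0, 1, 1),
                             imgWidth, imgHeight,
                             minAreaFrac = 0.25, minPixels = 2) {
  if (nrow(boxes) == 0L) return(boxes)
  x0 <- boxes$cx - boxes$w / 2
  x1 <- boxes$cx + boxes$w / 2
  y0 <- boxes$cy - boxes$h / 2
  y1 <- boxes$cy + boxes$h / 2
  cx0 <- pmax(x0, rect[1L]); cy0 <- pmax(y0, rect[2L])
  cx1 <- pmin(x1, rect[3L]); cy1 <- pmin(y1, rect[4L])
  cw <- cx1 - cx0
  ch <- cy1 - cy0
  keep <- cw > 0 & ch > 0
  area0 <- (x1 - x0) * (y1 - y0)
  ## inclusive at the threshold, with slack for floating-point roundoff
  keep <- keep & (cw * ch) >= minAreaFrac * area0 - 1e-12
  keep <- keep & cw * imgWidth >= minPixels & ch * imgHeight >= minPixels
  out <- boxes[keep, , drop = FALSE]
  if (nrow(out)) {
    out$cx <- (cx0[keep] + cx1[keep]) / 2
    out$cy <- (cy0[keep] + cy1[keep]) / 2
    out$w <- cw[keep]
    out$h <- ch[keep]
  }
  rownames(out) <- NULL
  out
}

.checkImage <- function(img) {
  if (!is(img, "AnnotatedImage"))
    stop("expected an AnnotatedImage", call. = FALSE)
  invisible(TRUE)
}
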