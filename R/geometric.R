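## Geometric operators: translation and rotation with exact box transforms.
## Pixel coordinates are continuous, origin at the top-left corner of the
## top-left pixel, x rightward, y downward; the center of pixel (row i,
## col j) sits at (j - 0.5, i - 0.5).

.DEFAULT_FILL <- c(114, 114, 114)

## Resample `src` ([H, W, 3]) at continuous source coordinates (xs, ys),
## one pair per destination pixel in column-major [outH, outW] order.
## Destination pixels whose source coordinate falls outside the canvas get
## the fill color; border samples clamp to the edge pixel.
.sampleImage <- function(src, xs, ys, outH, outW,
                         fill = .DEFAULT_FILL,
                         filter = c("bilinear", "nearest")) {
  filter <- match.arg(filter)
  H <- dim(src)[1L]; W <- dim(src)[2L]
  inside <- xs >= 0 & xs <= W & ys >= 0 & ys <= H
  out <- array(0, dim = c(outH, outW, 3L))
  if (filter == "nearest") {
    j <- pmin(pmax(floor(xs) + 1, 1), W)
    i <- pmin(pmax(floor(ys) + 1, 1), H)
    lin <- i + (j - 1) * H
    for (ch in 1:3) {
      sl <- src[, , ch]
      v <- sl[lin]
      v[!inside] <- fill[ch]
      out[, , ch] <- v
    }
  } else {
    u <- xs + 0.5  # pixel-center index space: center of col j is u = j
    v <- ys + 0.5
    j0 <- floor(u); i0 <- floor(v)
    fx <- u - j0; fy <- v - i0
    j0c <- pmin(pmax(j0, 1), W); j1c <- pmin(pmax(j0 + 1, 1), W)
    i0c <- pmin(pmax(i0, 1), H); i1c <- pmin(pmax(i0 + 1, 1), H)
    l00 <- i0c + (j0c - 1) * H; l01 <- i0c + (j1c - 1) * H
    l10 <- i1c + (j0c - 1) * H; l11 <- i1c + (j1c - 1) * H
    w00 <- (1 - fx) * (1 - fy); w01 <- fx * (1 - fy)
    w10 <- (1 - fx) * fy;       w11 <- fx * fy
    for (ch in 1:3) {
      sl <- src[, , ch]
      val <- w00 * sl[l00] + w01 * sl[l01] + w10 * sl[l10] + w11 * sl[l11]
      val[!inside] <- fill[ch]
      out[, , ch] <- val
    }
  }
  out
}

.resizeArray <- function(a, outH, outW, filter = "bilinear") {
  H <- dim(a)[1L]; W <- dim(a)[2L]
  if (H == outH && W == outW) return(a)
  cc <- rep(seq_len(outW), each = outH)
  rr <- rep(seq_len(outH), times = outW)
  xs <- (cc - 0.5) * W / outW
  ys <- (rr - 0.5) * H / outH
  .roundHalfUp(.sampleImage(a, xs, ys, outH, outW, filter = filter))
}

#' Translate an annotated image
#'
#' Shifts the pixel content by `(round(dx * width), round(dy * height))`
#' pixels on an unchanged canvas; vacated regions take the fill color.
#' Boxes are shifted by `(dx, dy)` in normalized units, clipped to the
#' canvas, and dropped when their clipped area falls below `minAreaFrac`
#' of the pre-clip area or either clipped side measures under 2 pixels.
#'
#' @param img an [AnnotatedImage-class].
#' @param dx,dy signed shifts as fractions of image width/height.
#' @param fill RGB fill color for vacated regions (default mid-gray
#'   114, 114, 114, the detector-family convention).
#' @param minAreaFrac visibility drop threshold (default 0.25).
#' @return a new `AnnotatedImage` with provenance `"translation"`.
#' @export
translateImage <- function(img, dx, dy, fill = .DEFAULT_FILL,
                           minAreaFrac = 0.25) {
  .checkImage(img)
  a <- imageArray(img)
  H <- dim(a)[1L]; W <- dim(a)[2L]
  sx <- round(dx * W); sy <- round(dy * H)
  out <- array(rep(fill, each = H * W), dim = c(H, W, 3L))
  r0 <- max(1, 1 + sy); r1 <- min(H, H + sy)
  c0 <- max(1, 1 + sx); c1 <- min(W, W + sx)
  if (r0 <= r1 && c0 <= c1)
    out[r0:r1, c0:c1, ] <- a[(r0:r1) - sy, (c0:c1) - sx, , drop = FALSE]
  bx <- boxes(img)
  if (nrow(bx)) {
    bx$cx <- bx$cx + dx
    bx$cy <- bx$cy + dy
    bx <- .clipBoxesToRect(bx, c(0, 0, 1, 1), W, H,
                           minAreaFrac = minAreaFrac)
  }
  AnnotatedImage(out, boxes = bx, id = imageId(img),
                 provenance = "translation",
                 meta = list(dx = dx, dy = dy, source = imageId(img)))
}

#' Rotate an annotated image about the canvas center
#'
#' Rotates by `theta` degrees (counter-clockwise positive in the y-down
#' image frame: at +90 degrees a point (x, y) in normalized square
#' coordinates maps to (y, 1 - x)). The canvas keeps its original size;
#' regions with no source pixel take the fill color. Each box's four
#' corners are rotated and the axis-aligned bounding box of the rotated
#' corners becomes the new annotation — a conservative cover, since the
#' YOLO format cannot express rotated boxes — then clipped with the same
#' visibility drop rule as [translateImage()].
#'
#' @param img an [AnnotatedImage-class].
#' @param theta rotation angle in degrees.
#' @param fill RGB fill color for out-of-source regions.
#' @param filter `"bilinear"` (default) or `"nearest"` resampling.
#' @param minAreaFrac visibility drop threshold (default 0.25).
#' @return a new `AnnotatedImage` with provenance `"rotation"`.
#' @export
rotateImage <- function(img, theta, fill = .DEFAULT_FILL,
                        filter = "bilinear", minAreaFrac = 0.25) {
  .checkImage(img)
  a <- imageArray(img)
  H <- dim(a)[1L]; W <- dim(a)[2L]
  rad <- theta * pi / 180
  ct <- cos(rad); st <- sin(rad)
  cxp <- W / 2; cyp <- H / 2
  ## inverse map: destination pixel center -> source coordinate
  cc <- rep(seq_len(W), each = H)
  rr <- rep(seq_len(H), times = W)
  xd <- cc - 0.5 - cxp
  yd <- rr - 0.5 - cyp
  xs <- cxp + xd * ct - yd * st
  ys <- cyp + xd * st + yd * ct
  out <- .roundHalfUp(.sampleImage(a, xs, ys, H, W, fill = fill,
                                   filter = filter))
  bx <- boxes(img)
  if (nrow(bx)) {
    px <- boxToPixel(bx, W, H)
    nb <- nrow(bx)
    corX <- cbind(px$x_min, px$x_max, px$x_max, px$x_min) - cxp
    corY <- cbind(px$y_min, px$y_min, px$y_max, px$y_max) - cyp
    ## forward rotation of the corners: (x, y) -> (x ct + y st, -x st + y ct)
    rx <- corX * ct + corY * st + cxp
    ry <- -corX * st + corY * ct + cyp
    rects <- data.frame(x_min = apply(rx, 1L, min),
                        y_min = apply(ry, 1L, min),
                        x_max = apply(rx, 1L, max),
                        y_max = apply(ry, 1L, max))
    bx <- pixelToBox(rects, W, H, class_id = bx$class_id)
    bx <- .clipBoxesToRect(bx, c(0, 0, 1, 1), W, H,
                           minAreaFrac = minAreaFrac)
  }
  AnnotatedImage(out, boxes = bx, id = imageId(img),
                 provenance = "rotation",
                 meta = list(theta = theta, source = imageId(img)))
}

#' Sample geometric augmentation parameters
#'
#' Draws from the default uniform laws: shifts `dx, dy ~ U(-0.2, 0.2)`
#' (at most 0.2 of the image size in either direction) and rotation angle
#' `theta ~ U(-90, 90)` degrees. Uses the current R random stream.
#'
#' @return list with elements `dx`, `dy`, `theta`.
#' @export
sampleGeometricParams <- function() {
  list(dx = runif(1, -0.2, 0.2), dy = runif(1, -0.2, 0.2),
       theta = runif(1, -90, 90))
}
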