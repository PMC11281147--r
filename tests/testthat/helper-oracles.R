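## Independent oracles and fixture builders. Everything here is written as
## naive scalar code, deliberately sharing no helpers with the package.

## uniform random test image as an AnnotatedImage
randomImage <- function(h = 16, w = 16, boxes = yoloBoxes(), id = "rnd") {
  a <- array(sample(0:255, h * w * 3, replace = TRUE), dim = c(h, w, 3))
  AnnotatedImage(a, boxes = boxes, id = id)
}

## a valid random box table, strictly inside the unit square (sides large
## enough to stay above the 2 px degeneracy rule on >= 24 px canvases)
randomBoxes <- function(n, classId = 0L) {
  w <- runif(n, 0.12, 0.4)
  h <- runif(n, 0.12, 0.4)
  data.frame(class_id = as.integer(rep_len(classId, n)),
             cx = runif(n, w / 2, 1 - w / 2),
             cy = runif(n, h / 2, 1 - h / 2), w = w, h = h)
}

## scalar-loop gamma correction oracle
oracleGamma <- function(a, gamma, gain = 1) {
  out <- a
  for (i in seq_len(dim(a)[1])) for (j in seq_len(dim(a)[2]))
    for (ch in 1:3) {
      v <- gain * (a[i, j, ch] / 255)^gamma
      v <- max(0, min(1, v))
      out[i, j, ch] <- floor(255 * v + 0.5)
    }
  out
}

## scalar-loop brightness-contrast oracle
oracleBrightnessContrast <- function(a, alpha, beta) {
  out <- a
  for (i in seq_len(dim(a)[1])) for (j in seq_len(dim(a)[2]))
    for (ch in 1:3) {
      v <- alpha * a[i, j, ch] + beta
      out[i, j, ch] <- floor(max(0, min(255, v)) + 0.5)
    }
  out
}

## scalar-loop integer pixel shift with constant fill
oracleShift <- function(a, sx, sy, fill = c(114, 114, 114)) {
  H <- dim(a)[1]; W <- dim(a)[2]
  out <- array(rep(fill, each = H * W), dim = dim(a))
  for (i in seq_len(H)) for (j in seq_len(W)) {
    si <- i - sy; sj <- j - sx
    if (si >= 1 && si <= H && sj >= 1 && sj <= W)
      out[i, j, ] <- a[si, sj, ]
  }
  out
}

## Rasterized-mask oracle for the rotated-box annotation: paint the box as
## a binary mask on a supersampled canvas grid, rotate the mask by
## inverse mapping each sample point, and return the tight bounds
## (x_min, y_min, x_max, y_max) of the surviving mask samples, or NULL if
## nothing lands on the canvas.
oracleRotatedBoxRect <- function(box, W, H, theta, ss = 4) {
  x0 <- (box$cx - box$w / 2) * W; x1 <- (box$cx + box$w / 2) * W
  y0 <- (box$cy - box$h / 2) * H; y1 <- (box$cy + box$h / 2) * H
  rad <- theta * pi / 180
  ct <- cos(rad); st <- sin(rad)
  cxp <- W / 2; cyp <- H / 2
  gx <- (seq_len(W * ss) - 0.5) / ss  # sample coordinates on the canvas
  gy <- (seq_len(H * ss) - 0.5) / ss
  px <- rep(gx, times = length(gy)) - cxp
  py <- rep(gy, each = length(gx)) - cyp
  ## rotate each destination sample back by -theta into the source frame
  xs <- cxp + px * ct - py * st
  ys <- cyp + px * st + py * ct
  hit <- xs >= x0 & xs <= x1 & ys >= y0 & ys <= y1
  if (!any(hit)) return(NULL)
  c(x_min = min(px[hit]) + cxp, y_min = min(py[hit]) + cyp,
    x_max = max(px[hit]) + cxp, y_max = max(py[hit]) + cyp)
}

## The mask oracle measures the on-canvas part of the rotated box; the
## package annotates the AABB of the rotated corners before clipping. The
## two coincide only when the rotated box stays on the canvas, so oracle
## comparisons are restricted to cases whose rotated corners all land at
## least `margin` pixels inside the canvas.
rotationStaysInterior <- function(box, W, H, theta, margin = 1) {
  x0 <- (box$cx - box$w / 2) * W; x1 <- (box$cx + box$w / 2) * W
  y0 <- (box$cy - box$h / 2) * H; y1 <- (box$cy + box$h / 2) * H
  rad <- theta * pi / 180
  cs <- cbind(c(x0, x1, x1, x0) - W / 2, c(y0, y0, y1, y1) - H / 2)
  rx <- cs[, 1] * cos(rad) + cs[, 2] * sin(rad) + W / 2
  ry <- -cs[, 1] * sin(rad) + cs[, 2] * cos(rad) + H / 2
  all(rx > margin & rx < W - margin & ry > margin & ry < H - margin)
}

## Independent greedy-matching oracle: naive loops, descending confidence
## (assumes distinct confidences), best-IoU assignment consuming the GT,
## TP iff best IoU >= t.
oracleMatch <- function(det, gt, t) {
  iou1 <- function(a, b) {
    ix <- max(0, min(a$cx + a$w / 2, b$cx + b$w / 2) -
                 max(a$cx - a$w / 2, b$cx - b$w / 2))
    iy <- max(0, min(a$cy + a$h / 2, b$cy + b$h / 2) -
                 max(a$cy - a$h / 2, b$cy - b$h / 2))
    inter <- ix * iy
    un <- a$w * a$h + b$w * b$h - inter
    if (un > 0) inter / un else 0
  }
  nd <- nrow(det); ng <- nrow(gt)
  tp <- logical(nd)
  free <- rep(TRUE, ng)
  for (d in order(-det$confidence)) {
    bestIou <- 0; bestG <- NA
    for (g in seq_len(ng)) {
      if (!free[g] || gt$class_id[g] != det$class_id[d]) next
      v <- iou1(det[d, ], gt[g, ])
      if (v > bestIou) { bestIou <- v; bestG <- g }
    }
    if (!is.na(bestG)) {
      free[bestG] <- FALSE
      tp[d] <- bestIou >= t
    }
  }
  tp
}

## absolute-tolerance box comparison (serialization is 6-decimal)
expect_boxes_close <- function(actual, expected, tol = 1e-6) {
  expect_equal(nrow(actual), nrow(expected))
  expect_identical(actual$class_id, expected$class_id)
  for (col in intersect(c("cx", "cy", "w", "h", "confidence"),
                        names(expected)))
    expect_lt(max(abs(actual[[col]] - expected[[col]]), 0), tol)
}

## tiny synthetic config used across tests
testSynthConfig <- function(size = 96)
  SynthConfig(imageSize = size, nInsects = c(2L, 6L), insectAxes = c(3, 8))
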