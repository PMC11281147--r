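test_that("translation shifts pixels and boxes consistently", {
  set.seed(201)
  img <- randomImage(20, 20, boxes = yoloBoxes(0L, 0.5, 0.5, 0.2, 0.2))

  idt <- translateImage(img, 0, 0)
  expect_identical(imageArray(idt), imageArray(img))
  expect_equal(boxes(idt), boxes(img))

  ## box fully exits the canvas
  gone <- translateImage(img, 0.6, 0)
  expect_equal(nBoxes(gone), 0L)

  ## worked shift example plus pixel-level oracle
  tr <- translateImage(img, 0.1, -0.05)
  expect_equal(boxes(tr)$cx, 0.6)
  expect_equal(boxes(tr)$cy, 0.45)
  expect_identical(imageArray(tr),
                   oracleShift(imageArray(img), round(0.1 * 20),
                               round(-0.05 * 20)))
  expect_equal(dim(tr), dim(img))
})

test_that("translate then inverse-translate restores unclipped boxes", {
  set.seed(202)
  for (i in 1:25) {
    bx <- randomBoxes(3)
    img <- randomImage(32, 32, boxes = bx)
    dx <- runif(1, -0.2, 0.2); dy <- runif(1, -0.2, 0.2)
    fwd <- translateImage(img, dx, dy)
    back <- translateImage(fwd, -dx, -dy)
    ## keep only boxes that never touched the border on the way out
    never <- bx$cx + dx + bx$w / 2 < 1 & bx$cx + dx - bx$w / 2 > 0 &
             bx$cy + dy + bx$h / 2 < 1 & bx$cy + dy - bx$h / 2 > 0
    restored <- boxes(back)
    for (b in which(never)) {
      hit <- which(abs(restored$cx - bx$cx[b]) < 1e-9 &
                   abs(restored$cy - bx$cy[b]) < 1e-9 &
                   abs(restored$w - bx$w[b]) < 1e-9 &
                   abs(restored$h - bx$h[b]) < 1e-9)
      expect_length(hit, 1L)
    }
  }
})

test_that("rotation maps boxes by exact corner arithmetic", {
  set.seed(203)
  img <- randomImage(40, 40, boxes = yoloBoxes(0L, 0.25, 0.25, 0.1, 0.2))

  id0 <- rotateImage(img, 0)
  expect_equal(boxes(id0), boxes(img), tolerance = 1e-12)
  expect_identical(imageArray(id0), imageArray(img))

  ## 90 degrees CCW on a square canvas: (x, y) -> (y, 1 - x)
  r90 <- rotateImage(img, 90)
  expect_equal(boxes(r90),
               yoloBoxes(0L, 0.25, 0.75, 0.2, 0.1), tolerance = 1e-9)

  ## 45 degrees on a centered square box: AABB side grows by sqrt(2)
  sq <- randomImage(40, 40, boxes = yoloBoxes(0L, 0.5, 0.5, 0.2, 0.2))
  r45 <- rotateImage(sq, 45)
  expect_equal(boxes(r45)$w, 0.2 * sqrt(2), tolerance = 1e-9)
  expect_equal(boxes(r45)$h, 0.2 * sqrt(2), tolerance = 1e-9)
  expect_equal(boxes(r45)$cx, 0.5, tolerance = 1e-9)
})

test_that("rotated boxes agree with the rasterized-mask oracle", {
  set.seed(204)
  W <- 48; H <- 48
  for (i in 1:40) {
    bx <- randomBoxes(1)
    theta <- runif(1, -90, 90)
    if (!rotationStaysInterior(bx, W, H, theta)) next
    img <- AnnotatedImage(array(128, dim = c(H, W, 3)), boxes = bx)
    out <- rotateImage(img, theta, minAreaFrac = 0)
    rect <- oracleRotatedBoxRect(bx, W, H, theta)
    if (is.null(rect) || nBoxes(out) == 0L) next
    got <- boxToPixel(boxes(out), W, H)
    expect_lt(abs(got$x_min - rect["x_min"]), 1.5)
    expect_lt(abs(got$y_min - rect["y_min"]), 1.5)
    expect_lt(abs(got$x_max - rect["x_max"]), 1.5)
    expect_lt(abs(got$y_max - rect["y_max"]), 1.5)
  }
})

test_that("the rotated AABB conservatively covers the rotated corners", {
  set.seed(205)
  for (i in 1:50) {
    bx <- randomBoxes(1)
    theta <- runif(1, -90, 90)
    img <- AnnotatedImage(array(100, dim = c(64, 64, 3)), boxes = bx)
    out <- rotateImage(img, theta, minAreaFrac = 0)
    if (nBoxes(out) == 0L) next
    ## rotate the true corners independently
    rad <- theta * pi / 180
    px <- boxToPixel(bx, 64, 64)
    cs <- cbind(c(px$x_min, px$x_max, px$x_max, px$x_min) - 32,
                c(px$y_min, px$y_min, px$y_max, px$y_max) - 32)
    rx <- cs[, 1] * cos(rad) + cs[, 2] * sin(rad) + 32
    ry <- -cs[, 1] * sin(rad) + cs[, 2] * cos(rad) + 32
    got <- boxToPixel(boxes(out), 64, 64)
    ## cover holds wherever the AABB was not clipped at the canvas
    tol <- 1e-9
    if (got$x_min > tol) expect_lte(got$x_min, min(rx) + tol)
    if (got$x_max < 64 - tol) expect_gte(got$x_max, max(rx) - tol)
    if (got$y_min > tol) expect_lte(got$y_min, min(ry) + tol)
    if (got$y_max < 64 - tol) expect_gte(got$y_max, max(ry) - tol)
  }
})

test_that("geometric parameter sampler follows the stated uniform laws", {
  set.seed(206)
  draws <- replicate(10000, unlist(sampleGeometricParams()))
  expect_true(all(abs(draws["dx", ]) <= 0.2))
  expect_true(all(abs(draws["dy", ]) <= 0.2))
  expect_true(all(abs(draws["theta", ]) <= 90))
  expect_gt(stats::ks.test(draws["dx", ], "punif", -0.2, 0.2)$p.value, 0.01)
  expect_gt(stats::ks.test(draws["theta", ], "punif", -90, 90)$p.value, 0.01)

  set.seed(4); s1 <- unlist(sampleGeometricParams())
  set.seed(4); s2 <- unlist(sampleGeometricParams())
  expect_identical(s1, s2)
})
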