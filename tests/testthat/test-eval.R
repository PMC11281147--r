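test_that("IoU matches closed-form and rasterized expectations", {
  b <- yoloBoxes(0L, 0.5, 0.5, 0.2, 0.2)
  expect_equal(boxIoU(b, b), 1.0)
  expect_equal(boxIoU(b, yoloBoxes(0L, 0.1, 0.1, 0.1, 0.1)), 0.0)
  ## pixel rects (0,0,2,2) and (1,1,3,3) on a 10x10 grid: intersection 1,
  ## union 7 (checked by counting cells on the integer grid)
  a1 <- pixelToBox(data.frame(x_min = 0, y_min = 0, x_max = 2, y_max = 2),
                   10, 10)
  a2 <- pixelToBox(data.frame(x_min = 1, y_min = 1, x_max = 3, y_max = 3),
                   10, 10)
  grid <- expand.grid(x = 0:9 + 0.5, y = 0:9 + 0.5)
  in1 <- grid$x > 0 & grid$x < 2 & grid$y > 0 & grid$y < 2
  in2 <- grid$x > 1 & grid$x < 3 & grid$y > 1 & grid$y < 3
  expect_equal(sum(in1 & in2) / sum(in1 | in2), 1 / 7)
  expect_equal(boxIoU(a1, a2), 1 / 7)
})

test_that("greedy matching applies the threshold and single-match rules", {
  gt <- yoloBoxes(0L, 0.5, 0.5, 0.2, 0.2)
  ## IoU 0.6 detection (overlap by construction)
  det <- yoloDetections(0L, 0.55, 0.5, 0.2, 0.2, 0.9)
  m <- matchDetections(det, gt, 0.5)
  expect_true(m$tp)
  expect_equal(m$nUnmatchedGt, 0L)

  ## two detections on one GT: higher confidence wins, other is FP
  det2 <- yoloDetections(c(0L, 0L), c(0.5, 0.52), c(0.5, 0.5),
                         c(0.2, 0.2), c(0.2, 0.2), c(0.7, 0.95))
  m2 <- matchDetections(det2, gt, 0.5)
  expect_equal(m2$tp, c(FALSE, TRUE))

  ## class mismatch never matches
  detc <- yoloDetections(1L, 0.5, 0.5, 0.2, 0.2, 0.9)
  expect_false(matchDetections(detc, gt, 0.5)$tp)
  expect_error(matchDetections(det, gt, 0), "threshold")
})

test_that("matching equals the independent small-instance oracle", {
  set.seed(401)
  for (i in 1:200) {
    ng <- sample(0:5, 1); nd <- sample(0:5, 1)
    gt <- if (ng) randomBoxes(ng, classId = sample(0:1, ng, TRUE)) else
      yoloBoxes()
    det <- if (nd) {
      d <- randomBoxes(nd, classId = sample(0:1, nd, TRUE))
      d$confidence <- sample(seq(0.05, 0.95, by = 0.01), nd)  # distinct
      d
    } else yoloDetections()
    t <- sample(c(0.3, 0.5, 0.7), 1)
    expect_identical(matchDetections(det, gt, t)$tp, oracleMatch(det, gt, t))
  }
})

test_that("PR accumulation reproduces the hand-enumerated example", {
  ## detections labeled (TP, FP, TP) in confidence order with 2 GT boxes
  curve <- precisionRecallCurve(confidence = c(0.9, 0.8, 0.7),
                                tp = c(TRUE, FALSE, TRUE), nGt = 2)
  expect_equal(curve$precision, c(1, 0.5, 2 / 3))
  expect_equal(curve$recall, c(0.5, 0.5, 1))
  expect_true(all(diff(curve$recall) >= 0))

  ## area under the interpolated envelope: 0.5 * 1 + 0.5 * (2/3) = 5/6
  expect_equal(averagePrecision(curve), 5 / 6)
  expect_equal(averagePrecision(curve, "101point"),
               mean(c(rep(1, 51), rep(2 / 3, 50))))

  perfect <- precisionRecallCurve(1, TRUE, 1)
  expect_equal(averagePrecision(perfect), 1.0)
  allFp <- precisionRecallCurve(c(0.9, 0.5), c(FALSE, FALSE), 3)
  expect_equal(allFp$precision, c(0, 0))
  expect_equal(averagePrecision(allFp), 0.0)
  expect_equal(averagePrecision(precisionRecallCurve(numeric(), logical(),
                                                     0)), 0)
})

test_that("perfect detections score mAP 1 and misses score 0", {
  set.seed(402)
  imgs <- generateSyntheticImages(4, testSynthConfig(64), seed = 23)
  gt <- lapply(imgs, boxes)
  names(gt) <- vapply(imgs, imageId, character(1))
  det <- lapply(gt, function(g) generateDetections(g))  # exact copies
  r <- evaluateDetections(det, gt)
  expect_equal(mAP50(r), 1.0)
  expect_equal(mAP50_95(r), 1.0)

  none <- lapply(gt, function(g) yoloDetections())
  r0 <- evaluateDetections(none, gt)
  expect_equal(mAP50(r0), 0.0)
  expect_equal(mAP50_95(r0), 0.0)

  expect_error(evaluateDetections(list(ghost = det[[1]]), gt), "unknown")
})

test_that("AP degrades monotonically with the IoU threshold", {
  set.seed(403)
  imgs <- generateSyntheticImages(4, testSynthConfig(64), seed = 29)
  gt <- lapply(imgs, boxes)
  names(gt) <- vapply(imgs, imageId, character(1))
  det <- lapply(gt, function(g)
    generateDetections(g, pMiss = 0.1, pSpurious = 1, jitterSd = 0.08))
  r <- evaluateDetections(det, gt)
  ap <- apValues(r)
  for (ci in seq_len(nrow(ap)))
    expect_true(all(diff(ap[ci, ]) <= 1e-9))
  expect_lte(mAP50_95(r), mAP50(r))
})

test_that("duplicate detections of one object do not raise AP", {
  gt <- list(im = yoloBoxes(0L, 0.5, 0.5, 0.2, 0.2))
  single <- list(im = yoloDetections(0L, 0.5, 0.5, 0.2, 0.2, 0.9))
  dup <- list(im = yoloDetections(c(0L, 0L), c(0.5, 0.5), c(0.5, 0.5),
                                  c(0.2, 0.2), c(0.2, 0.2), c(0.9, 0.8)))
  expect_lte(mAP50(evaluateDetections(dup, gt)),
             mAP50(evaluateDetections(single, gt)))
})

test_that("macro-averaging spans classes with ground truth", {
  gt <- list(im = yoloBoxes(c(0L, 1L), c(0.3, 0.7), c(0.3, 0.7),
                            c(0.2, 0.2), c(0.2, 0.2)))
  ## class 0 perfectly detected, class 1 missed entirely
  det <- list(im = yoloDetections(0L, 0.3, 0.3, 0.2, 0.2, 0.95))
  r <- evaluateDetections(det, gt)
  expect_equal(nrow(apValues(r)), 2L)
  expect_equal(mAP50(r), 0.5)
})
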