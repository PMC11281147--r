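centeredBoxImage <- function(size = 48, val = 128) {
  a <- array(val, dim = c(size, size, 3))
  AnnotatedImage(a, boxes = yoloBoxes(0L, 0.5, 0.5, 0.15, 0.15),
                 id = paste0("src", val))
}

test_that("mosaic center sampler respects offset bounds and law", {
  expect_equal(sampleMosaicCenter(0), c(0.5, 0.5))
  expect_error(sampleMosaicCenter(0.5), "0.5")
  set.seed(301)
  draws <- replicate(10000, sampleMosaicCenter(0.3))
  expect_true(all(draws >= 0.2 & draws <= 0.8))
  expect_gt(stats::ks.test(draws[1, ], "punif", 0.2, 0.8)$p.value, 0.01)
  expect_gt(stats::ks.test(draws[2, ], "punif", 0.2, 0.8)$p.value, 0.01)
})

test_that("centered mosaic of four identical sources is four corner crops", {
  src <- generateSyntheticImages(1, testSynthConfig(48), seed = 9)[[1]]
  srcs <- lapply(1:4, function(i) { imageId(src) <- paste0("s", i); src })
  m <- makeMosaic(srcs, center = c(0.5, 0.5), size = 48)
  a <- imageArray(m); s <- imageArray(src)
  expect_identical(a[1:24, 1:24, ], s[1:24, 1:24, ])
  expect_identical(a[1:24, 25:48, ], s[1:24, 25:48, ])
  expect_identical(a[25:48, 1:24, ], s[25:48, 1:24, ])
  expect_identical(a[25:48, 25:48, ], s[25:48, 25:48, ])
})

test_that("mosaic maps one centered box per source into its quadrant", {
  srcs <- lapply(c(60, 90, 120, 150), centeredBoxImage, size = 48)
  m <- makeMosaic(srcs, center = c(0.5, 0.5), size = 48)
  bx <- boxes(m)
  expect_equal(nrow(bx), 4L)
  ## each surviving box is the source's central box clipped to a quadrant
  quads <- list(c(0, 0, 0.5, 0.5), c(0.5, 0, 1, 0.5),
                c(0, 0.5, 0.5, 1), c(0.5, 0.5, 1, 1))
  for (q in 1:4) {
    b <- bx[q, ]
    r <- quads[[q]]
    expect_gte(b$cx - b$w / 2, r[1] - 1e-9)
    expect_lte(b$cx + b$w / 2, r[3] + 1e-9)
    expect_gte(b$cy - b$h / 2, r[2] - 1e-9)
    expect_lte(b$cy + b$h / 2, r[4] + 1e-9)
  }
})

test_that("off-center mosaic clips quadrants at the center line", {
  srcs <- lapply(c(60, 90, 120, 150), centeredBoxImage, size = 50)
  m <- makeMosaic(srcs, center = c(0.2, 0.5), size = 50,
                  minAreaFrac = 0)
  bx <- boxes(m)
  left <- bx[bx$cx < 0.2, , drop = FALSE]
  expect_true(all(left$cx + left$w / 2 <= 0.2 + 1e-9))
  expect_error(makeMosaic(srcs[1:3]), "4 source")
})

test_that("sources without boxes give a box-free mosaic", {
  srcs <- lapply(1:4, function(i) randomImage(24, 24, id = paste0("e", i)))
  set.seed(302)
  m <- makeMosaic(srcs)
  expect_equal(nBoxes(m), 0L)
})

test_that("seam containment and box conservation hold over random mosaics", {
  set.seed(303)
  for (i in 1:40) {
    sizes <- sample(32:56, 4, replace = TRUE)
    srcs <- lapply(1:4, function(q)
      randomImage(sizes[q], sizes[q], boxes = randomBoxes(sample(0:4, 1)),
                  id = paste0("r", q)))
    anchor <- sample(c("corner", "random"), 1)
    m <- makeMosaic(srcs, cropAnchor = anchor)
    nSrc <- sum(vapply(srcs, nBoxes, numeric(1)))
    expect_lte(nBoxes(m), nSrc)
    bx <- boxes(m)
    if (nrow(bx)) {
      expect_true(all(bx$cx - bx$w / 2 >= -1e-9))
      expect_true(all(bx$cx + bx$w / 2 <= 1 + 1e-9))
      expect_true(all(bx$cy - bx$h / 2 >= -1e-9))
      expect_true(all(bx$cy + bx$h / 2 <= 1 + 1e-9))
    }
  }
})

test_that("modified mosaic degenerates to the plain mosaic at p = (0, 0)", {
  srcs <- lapply(1:4, function(q)
    randomImage(32, 32, boxes = randomBoxes(2), id = paste0("d", q)))
  set.seed(304); plain <- makeMosaic(srcs)
  set.seed(304); mod <- makeModifiedMosaic(srcs, pBrightnessContrast = 0,
                                           pNoise = 0)
  expect_identical(imageArray(mod), imageArray(plain))
  expect_equal(boxes(mod), boxes(plain))
})

test_that("forced photometric transforms alter every quadrant", {
  srcs <- lapply(1:4, function(q)
    randomImage(32, 32, id = paste0("f", q)))
  set.seed(305); plain <- makeMosaic(srcs, center = c(0.5, 0.5))
  set.seed(305); mod <- makeModifiedMosaic(srcs, center = c(0.5, 0.5),
                                           pBrightnessContrast = 1,
                                           pNoise = 1)
  a <- imageArray(plain); b <- imageArray(mod)
  expect_false(identical(a[1:16, 1:16, ], b[1:16, 1:16, ]))
  expect_false(identical(a[1:16, 17:32, ], b[1:16, 17:32, ]))
  expect_false(identical(a[17:32, 1:16, ], b[17:32, 1:16, ]))
  expect_false(identical(a[17:32, 17:32, ], b[17:32, 17:32, ]))
  expect_equal(boxes(mod), boxes(plain))  # photometric leaves boxes alone
})

test_that("mosaics are bit-identical under a fixed seed", {
  srcs <- lapply(1:4, function(q)
    randomImage(28, 28, boxes = randomBoxes(2), id = paste0("s", q)))
  for (f in list(makeMosaic, makeModifiedMosaic)) {
    set.seed(306); m1 <- f(srcs)
    set.seed(306); m2 <- f(srcs)
    expect_identical(imageArray(m1), imageArray(m2))
    expect_equal(boxes(m1), boxes(m2))
  }
})

test_that("sub-image transform decisions follow the two Bernoulli laws", {
  set.seed(307)
  dec <- replicate(4000, {
    d <- sampleSubimageTransforms(0.8, 0.3)
    c(d$brightness_contrast, d$noise)
  })
  expect_lt(abs(mean(dec[1, ]) - 0.8), 0.03)
  expect_lt(abs(mean(dec[2, ]) - 0.3), 0.03)
})
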