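## Dataset enrichment: deterministic expansion of an original image set by
## one or more augmentation methods. The master seed derives one
## independent sub-seed per (method, pass, image), so adding or removing a
## method never perturbs another method's outputs — the property that makes
## method-by-method ablations reproducible.

#' Predict the size and composition of an enriched dataset
#'
#' Pure arithmetic, no I/O: with `n` originals, `m` distinct methods and
#' multiple `k`, the enriched set holds `n * (1 + k * m)` images when the
#' originals are included (each method contributes `k * n`), or `n * k * m`
#' otherwise.
#'
#' @param nOriginal number of original images (at least 1).
#' @param plan an [EnrichmentPlan-class].
#' @return list with `total`, `originals`, and named `perMethod` counts.
#' @examples
#' plan <- EnrichmentPlan(c("gamma", "brightness_contrast"), multiple = 1)
#' planEnrichment(330, plan)$total  # 990
#' @export
planEnrichment <- function(nOriginal, plan) {
  stopifnot(is(plan, "EnrichmentPlan"))
  validObject(plan)
  if (nOriginal < 1L) stop("nOriginal must be at least 1", call. = FALSE)
  per <- rep(plan@multiple * nOriginal, length(plan@methods))
  names(per) <- plan@methods
  orig <- if (plan@includeOriginals) nOriginal else 0L
  list(total = as.integer(orig + sum(per)), originals = as.integer(orig),
       perMethod = as.integer(per) |> stats::setNames(plan@methods))
}

.applyMethod <- function(method, img, sources = NULL, id = NULL,
                         mosaicSize = NULL) {
  switch(method,
    gamma = {
      p <- samplePhotometricParams()
      gammaCorrect(img, gamma = p$gamma, gain = p$gain)
    },
    brightness_contrast = {
      p <- samplePhotometricParams()
      brightnessContrast(img, alpha = p$alpha, beta = p$beta)
    },
    noise = addGaussianNoise(img),
    translation = {
      p <- sampleGeometricParams()
      translateImage(img, dx = p$dx, dy = p$dy)
    },
    rotation = {
      p <- sampleGeometricParams()
      rotateImage(img, theta = p$theta)
    },
    mosaic = makeMosaic(sources, size = mosaicSize, id = id),
    modified_mosaic = makeModifiedMosaic(sources, size = mosaicSize, id = id),
    stop("unknown method: ", method, call. = FALSE))
}

## Draw quads of distinct source indices for one mosaic pass: a seeded
## shuffle consumed four at a time, reshuffled when exhausted, so every
## image participates equally often.
.mosaicQuads <- function(n, nQuads) {
  pool <- sample.int(n)
  quads <- vector("list", nQuads)
  for (i in seq_len(nQuads)) {
    while (length(pool) < 4L) pool <- c(pool, sample.int(n))
    q <- unique(pool[1:4])
    take <- 4L
    while (length(q) < 4L) {  # duplicate across a shuffle boundary
      take <- take + 1L
      if (take > length(pool)) pool <- c(pool, sample.int(n))
      q <- unique(c(q, pool[take]))
    }
    pool <- pool[-match(q, pool)]
    quads[[i]] <- q
  }
  quads
}

#' Enrich a dataset according to a plan
#'
#' Runs every method in the plan for `multiple` passes over the originals.
#' Output order: the originals (when included), then per method and pass
#' one derivative per original image. Mosaic variants instead compose `n`
#' new images per pass from quadruples of distinct images drawn from a
#' seeded shuffle. Everything is driven by sub-seeds derived from the
#' plan's master seed, so identical inputs give bit-identical outputs.
#'
#' @param dataset non-empty list of [AnnotatedImage-class] objects; mosaic
#'   methods require at least 4.
#' @param plan an [EnrichmentPlan-class].
#' @param mosaicSize canvas side for mosaic outputs; `NULL` uses each
#'   quadruple's largest source dimension.
#' @return list of `AnnotatedImage`, of length `planEnrichment(...)$total`,
#'   with unique ids and provenance tags matching the generating method.
#' @export
enrichDataset <- function(dataset, plan, mosaicSize = NULL) {
  stopifnot(is(plan, "EnrichmentPlan"))
  validObject(plan)
  if (!is.list(dataset) || length(dataset) == 0L)
    stop("dataset must be a non-empty list of AnnotatedImage", call. = FALSE)
  lapply(dataset, .checkImage)
  n <- length(dataset)
  mosaicMethods <- intersect(plan@methods, c("mosaic", "modified_mosaic"))
  if (length(mosaicMethods) && n < 4L)
    stop("mosaic augmentation needs at least 4 images", call. = FALSE)
  out <- list()
  if (plan@includeOriginals) out <- dataset
  for (mi in seq_along(plan@methods)) {
    method <- plan@methods[mi]
    for (pass in seq_len(plan@multiple)) {
      if (method %in% c("mosaic", "modified_mosaic")) {
        set.seed(.deriveSeed(plan@seed, mi, pass, 0))
        quads <- .mosaicQuads(n, n)
        for (i in seq_len(n)) {
          set.seed(.deriveSeed(plan@seed, mi, pass, i))
          id <- sprintf("%s_k%d_%04d", method, pass, i)
          img <- .applyMethod(method, NULL, sources = dataset[quads[[i]]],
                              id = id, mosaicSize = mosaicSize)
          out[[length(out) + 1L]] <- img
        }
      } else {
        for (i in seq_len(n)) {
          set.seed(.deriveSeed(plan@seed, mi, pass, i))
          img <- .applyMethod(method, dataset[[i]])
          imageId(img) <- sprintf("%s_k%d_%s", method, pass,
                                  imageId(dataset[[i]]))
          out[[length(out) + 1L]] <- img
        }
      }
    }
  }
  out
}

#' Write an enriched dataset to disk with a provenance manifest
#'
#' Materializes the standard layout — `images/*.png`, `labels/*.txt` — plus
#' a `manifest.json` recording, per image, the id, provenance tag, source
#' ids and sampled parameters: a full audit trail from which the run can be
#' replayed.
#'
#' @param images list of [AnnotatedImage-class] objects with unique ids.
#' @param outDir output directory (created if needed).
#' @param extra named list merged into the manifest header (e.g. the plan's
#'   seed and methods).
#' @return invisibly, the manifest as a list.
#' @export
writeEnrichedDataset <- function(images, outDir, extra = list()) {
  if (length(images) == 0L)
    stop("no images to write", call. = FALSE)
  ids <- vapply(images, imageId, character(1))
  if (anyDuplicated(ids))
    stop("duplicate image ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  dir.create(file.path(outDir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(outDir, "labels"), recursive = TRUE,
             showWarnings = FALSE)
  entries <- vector("list", length(images))
  for (i in seq_along(images)) {
    img <- images[[i]]
    writeRasterImage(imageArray(img),
                     file.path(outDir, "images", paste0(imageId(img), ".png")))
    writeYoloAnnotation(boxes(img),
                        file.path(outDir, "labels",
                                  paste0(imageId(img), ".txt")))
    entries[[i]] <- c(list(id = imageId(img), provenance = provenance(img),
                           n_boxes = nBoxes(img)),
                      imageMeta(img))
  }
  manifest <- c(extra, list(n_images = length(images), images = entries))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
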