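#' Read a YOLO-format annotation or detection file
#'
#' Parses the sidecar text convention: one whitespace-separated line per
#' object, `class_id cx cy w h` (ground truth) or
#' `class_id cx cy w h confidence` (detections), all coordinates normalized
#' to image width/height.
#'
#' @param path path to the `.txt` sidecar file.
#' @param detection logical; expect six fields per line, the last being a
#'   confidence in \[0, 1\].
#' @return a box data.frame (see [yoloBoxes()]) or detection data.frame
#'   (see [yoloDetections()]); empty files give zero rows.
#' @export
readYoloAnnotation <- function(path, detection = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  nf <- if (detection) 6L else 5L
  if (length(lines) == 0L)
    return(if (detection) yoloDetections() else yoloBoxes())
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  lens <- lengths(parts)
  if (any(lens != nf)) {
    bad <- which(lens != nf)[1L]
    stop(sprintf("%s: line %d has %d fields, expected %d",
                 path, bad, lens[bad], nf), call. = FALSE)
  }
  m <- matrix(as.numeric(unlist(parts)), ncol = nf, byrow = TRUE)
  if (anyNA(m))
    stop(path, ": non-numeric field in annotation", call. = FALSE)
  df <- data.frame(class_id = as.integer(m[, 1L]),
                   cx = m[, 2L], cy = m[, 3L], w = m[, 4L], h = m[, 5L])
  if (detection) df$confidence <- m[, 6L]
  tryCatch(validateBoxes(df, detection = detection),
           error = function(e)
             stop(path, ": ", conditionMessage(e), call. = FALSE))
  df
}

#' Write boxes or detections in YOLO format
#'
#' Serializes to six decimal places, so a write/read round trip reproduces
#' the values to 1e-6.
#'
#' @param boxes a box or detection data.frame.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
writeYoloAnnotation <- function(boxes, path) {
  detection <- "confidence" %in% names(boxes)
  validateBoxes(boxes, detection = detection)
  if (nrow(boxes) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  fmt <- if (detection) "%d %.6f %.6f %.6f %.6f %.6f" else "%d %.6f %.6f %.6f %.6f"
  lines <- if (detection)
    sprintf(fmt, boxes$class_id, boxes$cx, boxes$cy, boxes$w, boxes$h,
            boxes$confidence)
  else
    sprintf(fmt, boxes$class_id, boxes$cx, boxes$cy, boxes$w, boxes$h)
  writeLines(lines, path)
  invisible(path)
}

#' Convert normalized boxes to continuous pixel rectangles
#'
#' Pixel coordinates are continuous with the origin at the top-left corner
#' of the top-left pixel, x rightward and y downward; a full-canvas box maps
#' to `(0, 0, width, height)`.
#'
#' @param boxes a box data.frame.
#' @param width,height image dimensions in pixels.
#' @return data.frame with columns `x_min`, `y_min`, `x_max`, `y_max`.
#' @export
boxToPixel <- function(boxes, width, height) {
  data.frame(x_min = (boxes$cx - boxes$w / 2) * width,
             y_min = (boxes$cy - boxes$h / 2) * height,
             x_max = (boxes$cx + boxes$w / 2) * width,
             y_max = (boxes$cy + boxes$h / 2) * height)
}

#' Convert pixel rectangles back to normalized boxes
#'
#' Exact inverse of [boxToPixel()].
#'
#' @param rects data.frame with `x_min`, `y_min`, `x_max`, `y_max`.
#' @param width,height image dimensions in pixels.
#' @param class_id class labels to attach (recycled).
#' @return a box data.frame.
#' @export
pixelToBox <- function(rects, width, height, class_id = 0L) {
  data.frame(class_id = as.integer(rep_len(class_id, nrow(rects))),
             cx = (rects$x_min + rects$x_max) / 2 / width,
             cy = (rects$y_min + rects$y_max) / 2 / height,
             w = (rects$x_max - rects$x_min) / width,
             h = (rects$y_max - rects$y_min) / height)
}

#' Read an 8-bit RGB raster image
#'
#' Supports PNG (always) and JPEG (when the `jpeg` package is installed).
#' Grayscale input is expanded to three channels; an alpha channel is
#' discarded.
#'
#' @param path image file path (`.png`, `.jpg`, `.jpeg`).
#' @return integer-valued array `[height, width, 3]` in 0..255.
#' @export
readRasterImage <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        stop("reading JPEG requires the 'jpeg' package", call. = FALSE)
      jpeg::readJPEG(path)
    },
    stop("unsupported image format: .", ext, call. = FALSE))
  if (length(dim(raw)) == 2L) raw <- array(raw, dim = c(dim(raw), 1L))
  if (dim(raw)[3L] == 1L) raw <- raw[, , c(1L, 1L, 1L), drop = FALSE]
  if (dim(raw)[3L] > 3L) raw <- raw[, , 1:3, drop = FALSE]
  .roundHalfUp(raw * 255)
}

#' Write an 8-bit RGB raster image as PNG
#'
#' PNG is the package's output format: lossless, so enrichment runs are
#' byte-reproducible.
#'
#' @param image integer-valued array `[height, width, 3]` in 0..255.
#' @param path output path (`.png`).
#' @return invisibly, `path`.
#' @export
writeRasterImage <- function(image, path) {
  png::writePNG(image / 255, path)
  invisible(path)
}

#' Read an annotated dataset from the images/labels directory layout
#'
#' Expects sibling `images/` and `labels/` directories with matching
#' basenames (`xyz.png` alongside `xyz.txt`). Images without a label file
#' get an empty box list.
#'
#' @param dir dataset root containing `images/` and `labels/`.
#' @return list of [AnnotatedImage-class] objects, ordered by file name.
#' @export
readDataset <- function(dir) {
  imgDir <- file.path(dir, "images")
  labDir <- file.path(dir, "labels")
  if (!dir.exists(imgDir))
    stop("no images/ directory under ", dir, call. = FALSE)
  files <- sort(list.files(imgDir, pattern = "\\.(png|jpe?g)$",
                           ignore.case = TRUE))
  if (length(files) == 0L)
    stop("no images found under ", imgDir, call. = FALSE)
  lapply(files, function(f) {
    base <- tools::file_path_sans_ext(f)
    lab <- file.path(labDir, paste0(base, ".txt"))
    bx <- if (file.exists(lab)) readYoloAnnotation(lab) else yoloBoxes()
    AnnotatedImage(readRasterImage(file.path(imgDir, f)), boxes = bx,
                   id = base)
  })
}

#' Per-channel intensity histograms of an image collection
#'
#' Pools all pixels of all images and returns, for each of the red, green
#' and blue channels, a normalized histogram over \[0, 255\]. Useful for
#' checking whether the channels share a similar color distribution (which
#' justifies applying one photometric mapping to all three).
#'
#' @param images list of [AnnotatedImage-class] objects.
#' @param bins number of equal-width bins over \[0, 255\] (at least 2).
#' @return matrix `bins x 3` with columns `red`, `green`, `blue`, each
#'   column summing to 1.
#' @export
channelHistograms <- function(images, bins = 32L) {
  if (length(images) == 0L)
    stop("need at least one image", call. = FALSE)
  if (bins < 2L) stop("bins must be at least 2", call. = FALSE)
  counts <- matrix(0, nrow = bins, ncol = 3L,
                   dimnames = list(NULL, c("red", "green", "blue")))
  width <- 256 / bins
  for (img in images) {
    .checkImage(img)
    a <- imageArray(img)
    for (ch in 1:3) {
      idx <- pmin(floor(a[, , ch] / width), bins - 1) + 1
      counts[, ch] <- counts[, ch] + tabulate(idx, nbins = bins)
    }
  }
  sweep(counts, 2L, colSums(counts), "/")
}
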