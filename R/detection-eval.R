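## Detection evaluation: IoU, greedy confidence-ordered matching,
## precision-recall curves, average precision, mAP50 and mAP50-95.

#' Intersection over union of two normalized boxes
#'
#' @param a,b single-row box data.frames (or lists with `cx`, `cy`, `w`,
#'   `h`) in the same coordinate space.
#' @return overlap area divided by union area, in \[0, 1\]; 0 when disjoint.
#' @export
boxIoU <- function(a, b) {
  .iouMatrix(data.frame(cx = a$cx, cy = a$cy, w = a$w, h = a$h),
             data.frame(cx = b$cx, cy = b$cy, w = b$w, h = b$h))[1L, 1L]
}

## IoU matrix between two box tables: rows index `a`, columns index `b`.
.iouMatrix <- function(a, b) {
  ax0 <- a$cx - a$w / 2; ax1 <- a$cx + a$w / 2
  ay0 <- a$cy - a$h / 2; ay1 <- a$cy + a$h / 2
  bx0 <- b$cx - b$w / 2; bx1 <- b$cx + b$w / 2
  by0 <- b$cy - b$h / 2; by1 <- b$cy + b$h / 2
  iw <- pmax(outer(ax1, bx1, pmin) - outer(ax0, bx0, pmax), 0)
  ih <- pmax(outer(ay1, by1, pmin) - outer(ay0, by0, pmax), 0)
  inter <- iw * ih
  areaA <- (ax1 - ax0) * (ay1 - ay0)
  areaB <- (bx1 - bx0) * (by1 - by0)
  un <- outer(areaA, areaB, "+") - inter
  ifelse(un > 0, inter / un, 0)
}

#' Greedy matching of detections to ground truth
#'
#' Detections are processed in descending confidence (ties broken by input
#' order); each is assigned to the not-yet-consumed ground-truth box of the
#' same class with the highest IoU (requiring positive overlap), which it
#' then consumes. The detection is a true positive when that best IoU
#' reaches the threshold, otherwise a false positive. Because the
#' assignment itself ignores the threshold, raising the threshold can only
#' demote true positives — AP is therefore non-increasing in the threshold.
#'
#' @param detections a detection data.frame ([yoloDetections()]).
#' @param groundTruth a box data.frame ([yoloBoxes()]).
#' @param threshold IoU threshold in (0, 1), default 0.5.
#' @return list with `tp` (logical per detection, in input order),
#'   `matchedGt` (index of consumed GT or `NA`), and `nUnmatchedGt`.
#' @export
matchDetections <- function(detections, groundTruth, threshold = 0.5) {
  validateBoxes(detections, detection = TRUE)
  validateBoxes(groundTruth)
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie in (0, 1)", call. = FALSE)
  nd <- nrow(detections)
  ng <- nrow(groundTruth)
  tp <- logical(nd)
  matched <- rep(NA_integer_, nd)
  gtFree <- rep(TRUE, ng)
  if (nd > 0L) {
    ord <- order(-detections$confidence)  # stable: ties keep input order
    iou <- if (ng > 0L) .iouMatrix(detections, groundTruth) else
      matrix(0, nd, 0L)
    for (d in ord) {
      if (ng == 0L) next
      cand <- which(gtFree & groundTruth$class_id == detections$class_id[d])
      if (length(cand) == 0L) next
      best <- cand[which.max(iou[d, cand])]
      if (iou[d, best] <= 0) next
      gtFree[best] <- FALSE
      matched[d] <- best
      tp[d] <- iou[d, best] >= threshold
    }
  }
  list(tp = tp, matchedGt = matched, nUnmatchedGt = sum(gtFree))
}

#' Precision-recall curve from pooled match outcomes
#'
#' Sweeps the pooled detections by descending confidence, accumulating true
#' and false positives; at each rank, precision = TP / (TP + FP) and
#' recall = TP / `nGt`.
#'
#' @param confidence detection confidences.
#' @param tp logical true-positive flags, aligned with `confidence`.
#' @param nGt total number of ground-truth boxes.
#' @return data.frame with columns `confidence`, `precision`, `recall`,
#'   one row per detection rank (zero rows when there are no detections).
#' @export
precisionRecallCurve <- function(confidence, tp, nGt) {
  stopifnot(length(confidence) == length(tp), nGt >= 0)
  if (length(confidence) == 0L)
    return(data.frame(confidence = numeric(), precision = numeric(),
                      recall = numeric()))
  ord <- order(-confidence)
  tp <- tp[ord]
  cumTp <- cumsum(tp)
  cumFp <- cumsum(!tp)
  data.frame(confidence = confidence[ord],
             precision = cumTp / (cumTp + cumFp),
             recall = if (nGt > 0) cumTp / nGt else rep(0, length(tp)))
}

#' Average precision from a precision-recall curve
#'
#' Area under the interpolated precision envelope: precision at recall `r`
#' is replaced by the maximum precision at any recall at least `r`, then
#' integrated over recall. `"all"` (default) integrates over every recall
#' change point; `"11point"` and `"101point"` average the envelope at
#' evenly spaced recall levels.
#'
#' @param curve data.frame from [precisionRecallCurve()].
#' @param method interpolation scheme.
#' @return AP in \[0, 1\]; an empty curve gives 0.
#' @export
averagePrecision <- function(curve, method = c("all", "11point", "101point")) {
  method <- match.arg(method)
  if (nrow(curve) == 0L) return(0)
  rec <- curve$recall
  prec <- curve$precision
  env <- rev(cummax(rev(prec)))  # envelope: max precision at recall >= r
  if (method == "all") {
    r <- c(0, rec)
    sum(diff(r) * env)
  } else {
    pts <- if (method == "11point") seq(0, 1, 0.1) else seq(0, 1, 0.01)
    vals <- vapply(pts, function(r) {
      i <- which(rec >= r - 1e-12)
      if (length(i)) max(env[i]) else 0
    }, numeric(1))
    mean(vals)
  }
}

#' Evaluate detections against ground truth over an IoU sweep
#'
#' Computes, per class and IoU threshold, the pooled-dataset average
#' precision, and reports mAP50 (mean over classes of AP at IoU 0.5) and
#' mAP50-95 (mean over classes and the thresholds 0.50, 0.55, ..., 0.95).
#' Classes are macro-averaged; classes present only in the detections
#' contribute no AP (no ground truth to recall).
#'
#' @param detections named list (by image id) of detection data.frames.
#' @param groundTruth named list (by image id) of box data.frames; defines
#'   the image set.
#' @param thresholds IoU thresholds, default `seq(0.5, 0.95, 0.05)`.
#' @param apMethod interpolation scheme for [averagePrecision()].
#' @return an [EvalResult-class].
#' @examples
#' gt <- list(img1 = yoloBoxes(0L, 0.5, 0.5, 0.2, 0.2))
#' det <- list(img1 = yoloDetections(0L, 0.5, 0.5, 0.2, 0.2, 1.0))
#' mAP50(evaluateDetections(det, gt))
#' @export
evaluateDetections <- function(detections, groundTruth,
                               thresholds = seq(0.5, 0.95, by = 0.05),
                               apMethod = "all") {
  if (is.null(names(groundTruth)) || any(!nzchar(names(groundTruth))))
    stop("groundTruth must be a named list (image ids)", call. = FALSE)
  unknown <- setdiff(names(detections), names(groundTruth))
  if (length(unknown))
    stop("detections reference unknown image ids: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  imgs <- names(groundTruth)
  classes <- sort(unique(unlist(lapply(groundTruth,
                                       function(g) g$class_id))))
  if (length(classes) == 0L) classes <- 0L
  ap <- matrix(0, nrow = length(classes), ncol = length(thresholds),
               dimnames = list(as.character(classes),
                               sprintf("%.2f", thresholds)))
  curves <- vector("list", length(classes))
  names(curves) <- as.character(classes)
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    nGt <- sum(vapply(groundTruth,
                      function(g) sum(g$class_id == cl), numeric(1)))
    for (ti in seq_along(thresholds)) {
      confs <- list(); tps <- list()
      for (im in imgs) {
        det <- detections[[im]]
        if (is.null(det)) det <- yoloDetections()
        det <- det[det$class_id == cl, , drop = FALSE]
        gt <- groundTruth[[im]]
        gt <- gt[gt$class_id == cl, , drop = FALSE]
        if (nrow(det) == 0L) next
        m <- matchDetections(det, gt, threshold = thresholds[ti])
        confs[[im]] <- det$confidence
        tps[[im]] <- m$tp
      }
      curve <- precisionRecallCurve(unlist(confs) %||% numeric(),
                                    unlist(tps) %||% logical(), nGt)
      if (ti == 1L) curves[[ci]] <- curve
      ap[ci, ti] <- if (nGt == 0L && nrow(curve) == 0L) 0 else
        averagePrecision(curve, method = apMethod)
    }
  }
  i50 <- which(abs(thresholds - 0.5) < 1e-9)
  map50 <- if (length(i50)) mean(ap[, i50[1L]]) else NA_real_
  sweepIdx <- which(thresholds >= 0.5 - 1e-9 & thresholds <= 0.95 + 1e-9)
  new("EvalResult", ap = ap, map50 = map50,
      map50_95 = mean(ap[, sweepIdx, drop = FALSE]),
      thresholds = thresholds, curves = curves)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
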