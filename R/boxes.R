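#' Construct a bounding-box table
#'
#' Boxes are stored as a plain `data.frame` with columns `min_x`, `min_y`,
#' `max_x`, `max_y`, and `confidence`. Annotation boxes carry
#' `confidence = NA`; prediction boxes carry a score in `[0, 1]`.
#'
#' @param min_x,min_y,max_x,max_y numeric vectors of box corners in pixel
#'   coordinates (origin top-left, x rightward, y downward).
#' @param confidence optional numeric vector of scores in `[0, 1]`, or `NA`
#'   for annotations.
#' @return a `data.frame` with one row per box.
#' @examples
#' boxes(0, 0, 10, 10)
#' boxes(c(0, 5), c(0, 0), c(10, 15), c(10, 10), confidence = c(0.9, 0.4))
#' @export
boxes <- function(min_x = numeric(), min_y = numeric(),
                  max_x = numeric(), max_y = numeric(),
                  confidence = NA_real_) {
  b <- data.frame(
    min_x = as.numeric(min_x), min_y = as.numeric(min_y),
    max_x = as.numeric(max_x), max_y = as.numeric(max_y),
    confidence = if (nrow2(min_x) == 0) numeric() else as.numeric(confidence)
  )
  validate_boxes(b)
  b
}

nrow2 <- function(x) length(x)

#' Validate a box table
#'
#' Enforces the box invariants: strictly positive width and height, and any
#' non-missing confidence within `[0, 1]`.
#'
#' @param b a box `data.frame` as produced by [boxes()].
#' @param require_conf if `TRUE`, every box must carry a non-missing
#'   confidence (predictions).
#' @return `b`, invisibly; errors describe the first offending row.
#' @export
validate_boxes <- function(b, require_conf = FALSE) {
  stopifnot(is.data.frame(b))
  needed <- c("min_x", "min_y", "max_x", "max_y")
  if (!all(needed %in% names(b))) {
    stop("box table must have columns min_x, min_y, max_x, max_y")
  }
  if (!"confidence" %in% names(b)) b$confidence <- NA_real_
  if (nrow(b) == 0) return(invisible(b))
  bad <- which(!(b$min_x < b$max_x & b$min_y < b$max_y))
  if (length(bad) > 0) {
    stop("degenerate box (non-positive width or height) at row ", bad[1])
  }
  conf <- b$confidence
  bad <- which(!is.na(conf) & (conf < 0 | conf > 1))
  if (length(bad) > 0) {
    stop("confidence outside [0, 1] at row ", bad[1])
  }
  if (require_conf && anyNA(conf)) {
    stop("all boxes must be scored (non-missing confidence)")
  }
  invisible(b)
}

#' Geometric area of each box
#'
#' @param b a box table.
#' @return numeric vector of areas `(max_x - min_x) * (max_y - min_y)`.
#' @export
box_area <- function(b) {
  (b$max_x - b$min_x) * (b$max_y - b$min_y)
}

#' Intersection-over-union of two boxes
#'
#' @param a,b single-row box tables (or lists with the four corner fields).
#' @return the IoU in `[0, 1]`; 0 when the boxes are disjoint.
#' @examples
#' iou(boxes(0, 0, 10, 10), boxes(5, 0, 15, 10)) # 50 / 150
#' @export
iou <- function(a, b) {
  a <- as.data.frame(a)[1, , drop = FALSE]
  b <- as.data.frame(b)[1, , drop = FALSE]
  validate_boxes(a)
  validate_boxes(b)
  drop(iou_matrix(a, b))
}

#' Pairwise IoU matrix between two box tables
#'
#' @param a,b box tables with `na` and `nb` rows.
#' @return an `na x nb` numeric matrix of IoU values.
#' @export
iou_matrix <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  if (na == 0 || nb == 0) return(matrix(0, na, nb))
  ix1 <- outer(a$min_x, b$min_x, pmax)
  iy1 <- outer(a$min_y, b$min_y, pmax)
  ix2 <- outer(a$max_x, b$max_x, pmin)
  iy2 <- outer(a$max_y, b$max_y, pmin)
  iw <- pmax(ix2 - ix1, 0)
  ih <- pmax(iy2 - iy1, 0)
  inter <- iw * ih
  union <- outer(box_area(a), box_area(b), `+`) - inter
  inter / union
}

#' Greedy non-maximum suppression
#'
#' Repeatedly keeps the highest-confidence remaining box and discards every
#' remaining box whose IoU with it strictly exceeds `iou_thresh`. Confidence
#' ties are broken by ascending input index. The output is sorted by
#' descending confidence.
#'
#' @param b a scored box table (all confidences present).
#' @param iou_thresh suppression threshold; the tiled-inference default is
#'   0.4.
#' @return the surviving boxes, ordered by descending confidence.
#' @export
nms <- function(b, iou_thresh = 0.4) {
  validate_boxes(b, require_conf = TRUE)
  if (nrow(b) <= 1) return(b)
  ord <- order(-b$confidence, seq_len(nrow(b)))
  b2 <- b[ord, , drop = FALSE]
  m <- iou_matrix(b2, b2)
  n <- nrow(b2)
  alive <- rep(TRUE, n)
  keep <- logical(n)
  for (i in seq_len(n)) {
    if (!alive[i]) next
    keep[i] <- TRUE
    alive[i] <- FALSE
    alive[alive & m[i, ] > iou_thresh] <- FALSE
  }
  out <- b2[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Evaluation thresholds for detection matching
#'
#' Defaults follow the wheat-head challenge convention: a prediction counts
#' only if its confidence strictly exceeds 0.5, and matches an annotation only
#' at IoU of at least 0.5.
#'
#' @param iou_min minimum IoU for a prediction/annotation match (inclusive).
#' @param conf_min confidence threshold for predictions.
#' @param exclusive_conf if `TRUE` (default) the confidence filter is strict
#'   (`> conf_min`); otherwise inclusive.
#' @return an object of class `eval_thresholds`.
#' @export
eval_thresholds <- function(iou_min = 0.5, conf_min = 0.5,
                            exclusive_conf = TRUE) {
  stopifnot(iou_min >= 0, iou_min <= 1, conf_min >= 0, conf_min <= 1)
  structure(list(iou_min = iou_min, conf_min = conf_min,
                 exclusive_conf = isTRUE(exclusive_conf)),
            class = "eval_thresholds")
}

#' Match predicted boxes against annotations
#'
#' Implements the matching that backs the per-image accuracy metric.
#' Predictions failing the confidence filter are discarded first. The
#' remaining predictions are processed in order of descending confidence
#' (ties broken by ascending input index); each is greedily matched to the
#' still-unmatched annotation with the highest IoU, provided that IoU reaches
#' `iou_min` (IoU ties broken by ascending annotation index). Unmatched
#' surviving predictions are false positives; unmatched annotations are false
#' negatives.
#'
#' @param predictions scored box table.
#' @param annotations box table (confidence ignored).
#' @param thresholds an [eval_thresholds()] object.
#' @return a `match_result`: list with integer counts `tp`, `fp`, `fn` and a
#'   `pairs` data.frame of matched (prediction, annotation) input indices.
#' @export
match_detections <- function(predictions, annotations,
                             thresholds = eval_thresholds()) {
  validate_boxes(predictions, require_conf = nrow(predictions) > 0)
  validate_boxes(annotations)
  t <- thresholds
  n_anno <- nrow(annotations)
  if (nrow(predictions) > 0) {
    keep <- if (t$exclusive_conf) predictions$confidence > t$conf_min
            else predictions$confidence >= t$conf_min
    kept_idx <- which(keep)
  } else {
    kept_idx <- integer()
  }
  n_pred <- length(kept_idx)
  pairs <- data.frame(prediction = integer(), annotation = integer())
  if (n_pred > 0 && n_anno > 0) {
    preds <- predictions[kept_idx, , drop = FALSE]
    ord <- order(-preds$confidence, seq_len(n_pred))
    m <- iou_matrix(preds, annotations)
    matched_anno <- rep(FALSE, n_anno)
    for (i in ord) {
      ious <- m[i, ]
      ious[matched_anno] <- -Inf
      j <- which.max(ious) # ties -> lowest annotation index
      if (is.finite(ious[j]) && ious[j] >= t$iou_min) {
        matched_anno[j] <- TRUE
        pairs <- rbind(pairs, data.frame(prediction = kept_idx[i],
                                         annotation = j))
      }
    }
    pairs <- pairs[order(pairs$prediction), , drop = FALSE]
    rownames(pairs) <- NULL
  }
  tp <- nrow(pairs)
  structure(list(tp = tp, fp = n_pred - tp, fn = n_anno - tp, pairs = pairs),
            class = "match_result")
}

#' Per-image detection accuracy
#'
#' The accuracy metric of the Global Wheat Head Detection challenge:
#' `TP / (TP + FN + FP)` for one image. An image with no annotations and no
#' confident predictions is scored 1.0 (the detector made no mistake).
#'
#' @param m a `match_result` from [match_detections()], or a list with
#'   fields `tp`, `fp`, `fn`.
#' @return a ratio in `[0, 1]`.
#' @export
image_accuracy <- function(m) {
  stopifnot(m$tp >= 0, m$fp >= 0, m$fn >= 0)
  denom <- m$tp + m$fn + m$fp
  if (denom == 0) return(1.0)
  m$tp / denom
}

#' Aggregate per-image accuracies to set level and split level
#'
#' Set accuracy is the unweighted mean of the accuracies of the images in the
#' set; split accuracy is the unweighted mean of the set accuracies (not a
#' pooled mean over images, so small sets weigh as much as large ones).
#'
#' @param accuracy numeric vector of per-image accuracies.
#' @param set parallel vector of image-set identifiers.
#' @return list with `per_set` (named numeric, in first-appearance order) and
#'   `split` (scalar mean of the per-set values).
#' @export
aggregate_accuracy <- function(accuracy, set) {
  if (length(accuracy) == 0) stop("no image accuracies to aggregate")
  if (length(accuracy) != length(set)) stop("accuracy and set lengths differ")
  set <- as.character(set)
  lv <- unique(set)
  per_set <- vapply(lv, function(s) mean(accuracy[set == s]), numeric(1))
  list(per_set = per_set, split = mean(per_set))
}

#' Mean absolute count error
#'
#' The counting metric: the mean over images of the absolute difference
#' between the number of confident predictions and the number of annotations.
#' It depends only on cardinalities, never on box geometry.
#'
#' @param n_pred,n_anno equal-length integer vectors of per-image prediction
#'   and annotation counts.
#' @return a nonnegative scalar.
#' @export
count_error <- function(n_pred, n_anno) {
  if (length(n_pred) != length(n_anno)) {
    stop("prediction and annotation count vectors must have equal length")
  }
  if (length(n_pred) == 0) stop("no images")
  mean(abs(n_pred - n_anno))
}
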