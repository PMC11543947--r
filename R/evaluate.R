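#' Tiled whole-image prediction
#'
#' Runs a detector over a 50%-overlap (by default) patch grid and merges the
#' per-patch predictions with [merge_patch_predictions()] (ownership filter
#' plus NMS at `nms_iou`).
#'
#' @param detector a `detector_contract`.
#' @param model a fitted model for the detector.
#' @param pixels full-image pixel array.
#' @param patch_size patch side length.
#' @param overlap inference overlap fraction (default 0.5).
#' @param nms_iou IoU threshold for the merge-stage suppression.
#' @return a scored box table in image coordinates.
#' @export
predict_image <- function(detector, model, pixels, patch_size,
                          overlap = 0.5, nms_iou = 0.4) {
  h <- dim(pixels)[1]; w <- dim(pixels)[2]
  grid <- plan_grid(w, h, patch_size, overlap)
  preds <- vector("list", nrow(grid$origins))
  for (k in seq_len(nrow(grid$origins))) {
    ox <- grid$origins$x[k]; oy <- grid$origins$y[k]
    crop <- pixels[(floor(oy) + 1):(floor(oy) + patch_size),
                   (floor(ox) + 1):(floor(ox) + patch_size), , drop = FALSE]
    preds[[k]] <- detector$predict(model, crop)
  }
  merge_patch_predictions(preds, grid, nms_iou)
}

#' Evaluate a fitted model on image sets
#'
#' Runs tiled inference on every image, matches predictions against
#' annotations, and returns one row per image with the accuracy metric and
#' the confident-prediction / annotation counts used by [count_error()].
#'
#' @param detector a `detector_contract`.
#' @param model a fitted model.
#' @param sets list of `image_set`s.
#' @param patch_size patch side length.
#' @param thresholds an [eval_thresholds()].
#' @param overlap,nms_iou tiled-inference settings.
#' @return data.frame with columns `set_id`, `image_id`, `accuracy`,
#'   `n_pred`, `n_anno`.
#' @export
evaluate_sets <- function(detector, model, sets, patch_size,
                          thresholds = eval_thresholds(),
                          overlap = 0.5, nms_iou = 0.4) {
  rows <- list()
  for (s in sets) {
    for (im in s$images) {
      pred <- predict_image(detector, model, im$pixels, patch_size,
                            overlap, nms_iou)
      m <- match_detections(pred, im$boxes, thresholds)
      conf_ok <- if (nrow(pred) == 0) logical(0)
                 else if (thresholds$exclusive_conf)
                   pred$confidence > thresholds$conf_min
                 else pred$confidence >= thresholds$conf_min
      rows[[length(rows) + 1]] <- data.frame(
        set_id = s$id, image_id = im$id,
        accuracy = image_accuracy(m),
        n_pred = sum(conf_ok), n_anno = nrow(im$boxes))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
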