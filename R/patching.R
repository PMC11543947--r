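#' Plan a patch grid over an image
#'
#' Computes the top-left corners of fixed-size square patches tiling an
#' image. The stride is `patch_size * (1 - overlap_fraction)`; if the last
#' origin along an axis does not reach the image edge, a final origin flush
#' with the edge is appended (duplicated coverage near the edge, no padding),
#' so every pixel is covered by at least one patch.
#'
#' @param image_width,image_height image dimensions in pixels.
#' @param patch_size side length of the square patches (default 416, the
#'   input size of compact single-stage detectors).
#' @param overlap_fraction fraction of patch overlap in `[0, 1)`; 0 for
#'   training patches, 0.5 for tiled inference.
#' @return a `patch_grid`: list with the dimensions, patch size, overlap,
#'   per-axis origin vectors `xs`/`ys`, and an `origins` data.frame in
#'   row-major order (y slow, x fast).
#' @examples
#' plan_grid(832, 832, 416, 0)$origins    # 4 patches
#' plan_grid(1000, 1000, 416, 0)$origins  # 9 patches, edge-shifted
#' @export
plan_grid <- function(image_width, image_height, patch_size = 416,
                      overlap_fraction = 0) {
  stopifnot(overlap_fraction >= 0, overlap_fraction < 1)
  if (patch_size > min(image_width, image_height)) {
    stop("patch_size (", patch_size, ") exceeds image dimensions (",
         image_width, "x", image_height, ")")
  }
  stride <- patch_size * (1 - overlap_fraction)
  axis_origins <- function(dim) {
    n <- floor((dim - patch_size) / stride + 1e-9)
    xs <- stride * (0:n)
    if (xs[length(xs)] + patch_size < dim - 1e-9) {
      xs <- c(xs, dim - patch_size)
    }
    xs
  }
  xs <- axis_origins(image_width)
  ys <- axis_origins(image_height)
  origins <- expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)
  structure(list(image_width = image_width, image_height = image_height,
                 patch_size = patch_size, overlap_fraction = overlap_fraction,
                 xs = xs, ys = ys, origins = origins),
            class = "patch_grid")
}

#' Extract patches (pixels plus transformed annotations) from an image
#'
#' Each annotation intersecting a patch is clipped to the patch; the clipped
#' box is kept iff its area is at least `keep_fraction` times the original
#' area (and strictly positive). Kept boxes are shifted into patch-local
#' coordinates.
#'
#' @param image a `field_image` (list with `id`, `pixels` array
#'   `(h, w, 3)`, and a `boxes` table in image coordinates; `pixels` may be
#'   `NULL` when only annotation geometry is needed).
#' @param grid a [plan_grid()] result for the image's dimensions.
#' @param keep_fraction minimum retained area fraction for a clipped
#'   annotation (default 0.5); 0 keeps every annotation with positive
#'   intersection.
#' @return a list of `patch_record`s: lists with `image_id`, `set_id`,
#'   `origin` `(x, y)`, `patch_size`, `pixels`, and patch-local `boxes`.
#' @export
extract_patches <- function(image, grid, keep_fraction = 0.5) {
  stopifnot(keep_fraction >= 0, keep_fraction <= 1)
  ps <- grid$patch_size
  anno <- image$boxes
  validate_boxes(anno)
  orig_area <- box_area(anno)
  out <- vector("list", nrow(grid$origins))
  for (k in seq_len(nrow(grid$origins))) {
    ox <- grid$origins$x[k]; oy <- grid$origins$y[k]
    px <- NULL
    if (!is.null(image$pixels)) {
      rows <- (floor(oy) + 1):(floor(oy) + ps)
      cols <- (floor(ox) + 1):(floor(ox) + ps)
      px <- image$pixels[rows, cols, , drop = FALSE]
    }
    b <- anno
    if (nrow(b) > 0) {
      cx1 <- pmax(b$min_x, ox); cy1 <- pmax(b$min_y, oy)
      cx2 <- pmin(b$max_x, ox + ps); cy2 <- pmin(b$max_y, oy + ps)
      inter <- pmax(cx2 - cx1, 0) * pmax(cy2 - cy1, 0)
      keep <- inter > 0 & inter >= keep_fraction * orig_area - 1e-12
      b <- data.frame(min_x = cx1[keep] - ox, min_y = cy1[keep] - oy,
                      max_x = cx2[keep] - ox, max_y = cy2[keep] - oy,
                      confidence = rep(NA_real_, sum(keep)))
    }
    out[[k]] <- structure(
      list(image_id = image$id, set_id = image$set_id,
           domain_id = image$domain_id,
           origin = c(x = ox, y = oy), patch_size = ps,
           pixels = px, boxes = b),
      class = "patch_record")
  }
  out
}

rot90_cw <- function(m) t(m[nrow(m):1, , drop = FALSE])

apply_plane <- function(px, f) {
  if (is.null(px)) return(NULL)
  out <- array(0, dim = dim(px)) # square patches: shape preserved
  for (ch in seq_len(dim(px)[3])) out[, , ch] <- f(px[, , ch])
  out
}

#' Randomly augment a training patch
#'
#' Applies, in fixed order, a single 90-degree clockwise rotation, a
#' horizontal flip, and a vertical flip, each independently with probability
#' 0.5, to pixels and annotation boxes consistently. The three transforms
#' generate the dihedral symmetries of the square. Draws come from the
#' current RNG stream; individual transforms can be forced for testing.
#'
#' @param patch a square `patch_record`.
#' @param rotate,hflip,vflip `NULL` (draw with probability 0.5) or a logical
#'   forcing the transform on/off.
#' @return the augmented `patch_record`.
#' @export
augment_patch <- function(patch, rotate = NULL, hflip = NULL, vflip = NULL) {
  if (!is.null(patch$pixels) && dim(patch$pixels)[1] != dim(patch$pixels)[2]) {
    stop("augment_patch requires a square patch")
  }
  s <- patch$patch_size
  if (is.null(rotate)) rotate <- stats::runif(1) < 0.5
  if (is.null(hflip)) hflip <- stats::runif(1) < 0.5
  if (is.null(vflip)) vflip <- stats::runif(1) < 0.5
  b <- patch$boxes
  px <- patch$pixels
  if (rotate) { # (x, y) -> (s - y, x)
    b <- data.frame(min_x = s - b$max_y, min_y = b$min_x,
                    max_x = s - b$min_y, max_y = b$max_x,
                    confidence = b$confidence)
    px <- apply_plane(px, rot90_cw)
  }
  if (hflip) { # x -> s - x
    b <- data.frame(min_x = s - b$max_x, min_y = b$min_y,
                    max_x = s - b$min_x, max_y = b$max_y,
                    confidence = b$confidence)
    px <- apply_plane(px, function(m) m[, ncol(m):1, drop = FALSE])
  }
  if (vflip) { # y -> s - y
    b <- data.frame(min_x = b$min_x, min_y = s - b$max_y,
                    max_x = b$max_x, max_y = s - b$min_y,
                    confidence = b$confidence)
    px <- apply_plane(px, function(m) m[nrow(m):1, , drop = FALSE])
  }
  patch$boxes <- b
  patch$pixels <- px
  patch
}

#' Merge per-patch predictions back into image coordinates
#'
#' Three steps: (1) translate each patch's predictions into image
#' coordinates; (2) apply the ownership filter: the image is partitioned into
#' cells by nearest patch center (Euclidean distance, ties to the lower
#' row-major patch index) and a prediction survives only if its center lies
#' in its source patch's cell — this removes the duplicate detections that
#' 50%-overlap tiling produces while guaranteeing that every image location
#' is owned by exactly one patch; (3) greedy [nms()] at `nms_iou` over the
#' survivors.
#'
#' @param patch_preds list of scored box tables in patch-local coordinates,
#'   aligned with `grid$origins` rows.
#' @param grid the inference [plan_grid()].
#' @param nms_iou IoU threshold for the final suppression (default 0.4).
#' @return a scored box table in image coordinates.
#' @export
merge_patch_predictions <- function(patch_preds, grid, nms_iou = 0.4) {
  if (length(patch_preds) != nrow(grid$origins)) {
    stop("patch_preds must have one element per grid patch")
  }
  ps <- grid$patch_size
  centers_x <- grid$origins$x + ps / 2
  centers_y <- grid$origins$y + ps / 2
  all_boxes <- list()
  for (k in seq_along(patch_preds)) {
    b <- patch_preds[[k]]
    if (is.null(b) || nrow(b) == 0) next
    validate_boxes(b, require_conf = TRUE)
    if (any(b$min_x < -1e-9 | b$min_y < -1e-9 |
            b$max_x > ps + 1e-9 | b$max_y > ps + 1e-9)) {
      stop("prediction outside its source patch bounds (patch ", k, ")")
    }
    gb <- data.frame(min_x = b$min_x + grid$origins$x[k],
                     min_y = b$min_y + grid$origins$y[k],
                     max_x = b$max_x + grid$origins$x[k],
                     max_y = b$max_y + grid$origins$y[k],
                     confidence = b$confidence)
    cx <- (gb$min_x + gb$max_x) / 2
    cy <- (gb$min_y + gb$max_y) / 2
    owner <- vapply(seq_along(cx), function(i) {
      d2 <- (centers_x - cx[i])^2 + (centers_y - cy[i])^2
      which.min(d2) # ties -> lowest row-major index
    }, integer(1))
    all_boxes[[length(all_boxes) + 1]] <- gb[owner == k, , drop = FALSE]
  }
  if (length(all_boxes) == 0) {
    return(boxes())
  }
  merged <- do.call(rbind, all_boxes)
  rownames(merged) <- NULL
  nms(merged, nms_iou)
}
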