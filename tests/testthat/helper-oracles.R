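# Independent oracles coded from first principles, deliberately kept free of
# the package's own geometry helpers so they can referee them.

# IoU by counting unit pixels on an integer grid.
raster_iou <- function(a, b) {
  lim <- max(a$max_x, b$max_x, a$max_y, b$max_y)
  cells_x <- 0:(lim - 1)
  in_box <- function(box) {
    outer(cells_x, cells_x,
          function(x, y) x >= box$min_x & x < box$max_x &
                         y >= box$min_y & y < box$max_y)
  }
  ma <- in_box(a); mb <- in_box(b)
  inter <- sum(ma & mb)
  uni <- sum(ma | mb)
  if (uni == 0) 0 else inter / uni
}

# Scalar IoU, written out longhand.
simple_iou <- function(ax1, ay1, ax2, ay2, bx1, by1, bx2, by2) {
  iw <- min(ax2, bx2) - max(ax1, bx1)
  ih <- min(ay2, by2) - max(ay1, by1)
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  inter / ((ax2 - ax1) * (ay2 - ay1) + (bx2 - bx1) * (by2 - by1) - inter)
}

# Brute-force re-implementation of the stated matching policy: filter by
# strict confidence, process predictions in descending confidence (ties by
# input index), greedily take the unmatched annotation with the highest IoU
# if it reaches iou_min (IoU ties by lowest annotation index).
brute_match <- function(pred, anno, iou_min = 0.5, conf_min = 0.5) {
  kept <- which(pred$confidence > conf_min)
  n_anno <- nrow(anno)
  used <- rep(FALSE, n_anno)
  tp <- 0
  if (length(kept) > 0) {
    ord <- kept[order(-pred$confidence[kept], kept)]
    for (i in ord) {
      best_j <- 0; best_iou <- -1
      for (j in seq_len(n_anno)) {
        if (used[j]) next
        v <- simple_iou(pred$min_x[i], pred$min_y[i],
                        pred$max_x[i], pred$max_y[i],
                        anno$min_x[j], anno$min_y[j],
                        anno$max_x[j], anno$max_y[j])
        if (v > best_iou) { best_iou <- v; best_j <- j }
      }
      if (best_j > 0 && best_iou >= iou_min) {
        used[best_j] <- TRUE
        tp <- tp + 1
      }
    }
  }
  list(tp = tp, fp = length(kept) - tp, fn = n_anno - tp)
}

# Random valid integer boxes in [0, lim]^2.
random_int_boxes <- function(n, lim = 20, conf = NULL) {
  x1 <- sample(0:(lim - 1), n, replace = TRUE)
  y1 <- sample(0:(lim - 1), n, replace = TRUE)
  x2 <- x1 + sample(1:(lim %/% 2), n, replace = TRUE)
  y2 <- y1 + sample(1:(lim %/% 2), n, replace = TRUE)
  data.frame(min_x = x1, min_y = y1, max_x = pmin(x2, lim),
             max_y = pmin(y2, lim),
             confidence = if (is.null(conf)) NA_real_
                          else sample(conf, n, replace = TRUE))
}

# A uniform patch filled with a flat color; used to paint toy scenes.
flat_patch <- function(size, rgb = c(0.45, 0.40, 0.33)) {
  px <- array(0, dim = c(size, size, 3))
  for (ch in 1:3) px[, , ch] <- rgb[ch]
  px
}

# Paint an axis-aligned green rectangle (a toy "plant") onto a pixel array.
paint_rect <- function(px, min_x, min_y, max_x, max_y,
                       rgb = c(0.12, 0.65, 0.10)) {
  rows <- (min_y + 1):max_y
  cols <- (min_x + 1):max_x
  for (ch in 1:3) px[rows, cols, ch] <- rgb[ch]
  px
}

# Minimal in-memory field image.
toy_image <- function(boxes_df, width, height, pixels = NULL, id = "toy") {
  structure(list(id = id, domain_id = "toydom", set_id = "toyset",
                 width = width, height = height, pixels = pixels,
                 boxes = boxes_df, meta = list()),
            class = "field_image")
}

# An easy single-domain configuration: sparse stand, no occluders or weeds,
# mild blur and noise. Used to establish the detector's accuracy floor.
easy_domain_params <- function(seed = 42) {
  rng <- domain_ranges("train")
  rng$plant_rate <- c(12, 12)
  rng$weed_rate <- c(0, 0)
  rng$stubble_rate <- c(0, 0)
  rng$blur_sigma <- c(0.3, 0.4)
  rng$leaf_max <- c(2, 2)
  rng$noise_sd <- c(0.010, 0.015)
  rng$cotyledon_len <- c(6.5, 7.5)
  sample_domain_params(seed, rng)
}

# Small benchmark for pipeline tests (kept tiny; experiments tests scale it).
tiny_benchmark <- function(seed = 5, k_train = 2, k_ood = 2,
                           n_train_images = 4, n_id = 2, n_ood = 2) {
  build_benchmark(k_train = k_train, k_ood = k_ood,
                  n_train_images = n_train_images, n_id_images = n_id,
                  n_ood_images = n_ood, width = 192, height = 192,
                  patch_size = 96, seed = seed)
}
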