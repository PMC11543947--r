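#' Excess-green vegetation index
#'
#' Per pixel, the chromatic coordinates `r, g, b` are the RGB channels
#' normalized by their sum (0 where the sum is 0), and the index is
#' `2g - r - b`, which lies in `[-1, 2]`. The normalization makes the index
#' invariant to multiplicative illumination changes, which is why it is the
#' standard first step for separating canopy from soil in field imagery.
#'
#' @param pixels numeric array `(h, w, 3)` in `[0, 1]`.
#' @return an `h x w` numeric matrix.
#' @examples
#' px <- array(0, c(1, 1, 3)); px[1, 1, 2] <- 1
#' exg_index(px) # pure green -> 2
#' @export
exg_index <- function(pixels) {
  s <- pixels[, , 1] + pixels[, , 2] + pixels[, , 3]
  num <- 2 * pixels[, , 2] - pixels[, , 1] - pixels[, , 3]
  num / (s + (s < 1e-12)) # zero-sum pixels map to 0
}

# 3x3 box erosion/dilation via shifted logical masks (separable passes).
shift_and <- function(m) {
  n <- nrow(m)
  up <- rbind(m[-1, , drop = FALSE], FALSE)
  down <- rbind(FALSE, m[-n, , drop = FALSE])
  m & up & down
}

binary_open3 <- function(mask) {
  er <- t(shift_and(t(shift_and(mask))))
  n <- nrow(er)
  up <- rbind(er[-1, , drop = FALSE], FALSE)
  down <- rbind(FALSE, er[-n, , drop = FALSE])
  v <- er | up | down
  t_v <- t(v)
  up2 <- rbind(t_v[-1, , drop = FALSE], FALSE)
  down2 <- rbind(FALSE, t_v[-nrow(t_v), , drop = FALSE])
  t(t_v | up2 | down2)
}

#' Propose candidate boxes by vegetation segmentation
#'
#' Thresholds the excess-green index at `tau`, cleans the binary mask with a
#' 3x3 morphological opening, labels 4-connected components, and returns
#' each component's tight bounding box together with shape statistics used
#' as classifier features. Components outside `[min_area, max_area]` pixels
#' are dropped.
#'
#' @param exg an index matrix from [exg_index()].
#' @param tau segmentation threshold (index units).
#' @param min_area,max_area component size filter, in pixels.
#' @return a data.frame with box columns (`min_x` ... `max_y`,
#'   `confidence = NA`) plus `area_px`, `fill`, `elongation` per component.
#' @export
propose_candidates <- function(exg, tau, min_area = 6, max_area = 2500) {
  mask <- exg > tau
  if (!any(mask)) return(cbind(boxes(), data.frame(area_px = numeric(),
                                                   fill = numeric(),
                                                   elongation = numeric())))
  opened <- binary_open3(mask)
  lab <- EBImage::bwlabel(opened)
  nlab <- max(lab)
  if (nlab == 0) return(cbind(boxes(), data.frame(area_px = numeric(),
                                                  fill = numeric(),
                                                  elongation = numeric())))
  h <- nrow(exg)
  idx <- which(lab > 0)
  lb <- lab[idx]
  rr <- ((idx - 1L) %% h) + 1L
  cc <- ((idx - 1L) %/% h) + 1L
  # grouped stats per label (labels are 1..nlab)
  n <- tabulate(lb, nlab)
  sum_r <- rowsum_vec(rr, lb, nlab); sum_c <- rowsum_vec(cc, lb, nlab)
  sum_rr <- rowsum_vec(rr * rr, lb, nlab)
  sum_cc <- rowsum_vec(cc * cc, lb, nlab)
  sum_rc <- rowsum_vec(rr * cc, lb, nlab)
  min_r <- group_min(rr, lb, nlab); max_r <- -group_min(-rr, lb, nlab)
  min_c <- group_min(cc, lb, nlab); max_c <- -group_min(-cc, lb, nlab)
  mu_r <- sum_r / n; mu_c <- sum_c / n
  v_rr <- sum_rr / n - mu_r^2 + 1 / 12 # pixel cells, not point masses
  v_cc <- sum_cc / n - mu_c^2 + 1 / 12
  v_rc <- sum_rc / n - mu_r * mu_c
  tr <- v_rr + v_cc
  det2 <- v_rr * v_cc - v_rc^2
  disc <- pmax(tr^2 / 4 - det2, 0)
  l1 <- tr / 2 + sqrt(disc); l2 <- pmax(tr / 2 - sqrt(disc), 1e-6)
  b <- data.frame(min_x = min_c - 1, min_y = min_r - 1,
                  max_x = max_c, max_y = max_r,
                  confidence = NA_real_,
                  area_px = n,
                  fill = n / ((max_c - min_c + 1) * (max_r - min_r + 1)),
                  elongation = sqrt(l1 / l2))
  b <- b[b$area_px >= min_area & b$area_px <= max_area, , drop = FALSE]
  rownames(b) <- NULL
  b
}

rowsum_vec <- function(x, g, nlab) {
  out <- numeric(nlab)
  rs <- rowsum(x, g)
  out[as.integer(rownames(rs))] <- rs[, 1]
  out
}

group_min <- function(x, g, nlab) {
  o <- order(g, x)
  first <- !duplicated(g[o])
  out <- numeric(nlab)
  out[g[o][first]] <- x[o][first]
  out
}

#' Feature vector for one candidate box
#'
#' Fixed-order features: log box area, aspect ratio (width/height), fill
#' ratio (vegetation pixels / box area at threshold `tau`), mean and
#' standard deviation of the excess-green index inside the box, contrast of
#' the inside mean against a 4-pixel surrounding ring, and the elongation of
#' the vegetation pixels' second moments. The three index-based features are
#' expressed *relative to the patch's own vegetation scale* (its 99th index
#' percentile, floored at 0.2): blur and lighting shift an individual patch's
#' absolute index values but move the numerator and the scale together, so
#' the ratios transfer across domains far better than raw values. Values are
#' otherwise unnormalized; the detector model z-scores them with stored
#' training statistics.
#'
#' @param pixels patch pixel array, or `NULL` if `exg` is supplied.
#' @param candidate single-row box table, inside the patch.
#' @param tau vegetation threshold defining "vegetation pixels".
#' @param exg optional precomputed index matrix (avoids recomputation).
#' @param veg_scale optional precomputed patch vegetation scale.
#' @return a named numeric vector of length 7.
#' @export
candidate_features <- function(pixels, candidate, tau, exg = NULL,
                               veg_scale = NULL) {
  if (is.null(exg)) exg <- exg_index(pixels)
  if (is.null(veg_scale)) veg_scale <- patch_veg_scale(exg)
  b <- as.data.frame(candidate)[1, , drop = FALSE]
  features_num(exg, veg_scale, tau, b$min_x, b$min_y, b$max_x, b$max_y)
}

features_num <- function(exg, veg_scale, tau, mnx, mny, mxx, mxy) {
  h <- nrow(exg); w <- ncol(exg)
  if (mnx < -1e-9 || mny < -1e-9 || mxx > w + 1e-9 || mxy > h + 1e-9) {
    stop("candidate box outside the patch")
  }
  r0 <- floor(mny) + 1L; r1 <- max(r0, ceiling(mxy))
  c0 <- floor(mnx) + 1L; c1 <- max(c0, ceiling(mxx))
  r1 <- min(r1, h); c1 <- min(c1, w)
  inside <- exg[r0:r1, c0:c1, drop = FALSE]
  veg <- inside > tau
  area <- (mxx - mnx) * (mxy - mny)
  aspect <- (mxx - mnx) / (mxy - mny)
  fill <- sum(veg) / length(inside)
  mu_in <- mean(inside)
  sd_in <- if (length(inside) > 1) stats::sd(inside) else 0
  ring <- 4L
  R0 <- max(1L, r0 - ring); R1 <- min(h, r1 + ring)
  C0 <- max(1L, c0 - ring); C1 <- min(w, c1 + ring)
  outer_block <- exg[R0:R1, C0:C1, drop = FALSE]
  ring_sum <- sum(outer_block) - sum(inside)
  ring_n <- length(outer_block) - length(inside)
  contrast <- if (ring_n > 0) mu_in - ring_sum / ring_n else 0
  # elongation of the vegetation pixels inside the box
  if (sum(veg) >= 2) {
    vr <- row(veg)[veg]; vc <- col(veg)[veg]
    v_rr <- stats::var(vr) + 1 / 12; v_cc <- stats::var(vc) + 1 / 12
    v_rc <- stats::cov(vr, vc)
    tr <- v_rr + v_cc
    disc <- max(tr^2 / 4 - (v_rr * v_cc - v_rc^2), 0)
    l1 <- tr / 2 + sqrt(disc); l2 <- max(tr / 2 - sqrt(disc), 1e-6)
    elong <- sqrt(l1 / l2)
  } else {
    elong <- 1
  }
  c(area = log(area), aspect = aspect, fill = fill,
    exg_mean = mu_in / veg_scale, exg_sd = sd_in / veg_scale,
    contrast = contrast / veg_scale, elongation = elong)
}

patch_veg_scale <- function(exg) {
  max(stats::quantile(exg, 0.99, names = FALSE), 0.2)
}

#' Reference detector configuration
#'
#' @param tau_probs quantile probabilities of the pooled index distribution
#'   searched for the vegetation threshold.
#' @param tau_patches number of (randomly chosen) training patches used for
#'   the threshold grid search; `NULL` (the default) scales the subsample
#'   with the pool — one in eight patches, between 12 and 256 — so threshold
#'   estimation genuinely improves with training-set size.
#' @param min_area,max_area component size filter in pixels.
#' @param label_iou IoU at which a candidate counts as a true seedling when
#'   labeling training candidates.
#' @param gd_iters,learning_rate,l2 full-batch gradient-descent settings for
#'   the logistic score model.
#' @param max_exemplars cap on the stored training exemplars behind the
#'   kernel-purity feature (a seeded subsample beyond the cap).
#' @param max_fit_patches cap on the training patches entering the
#'   score-model fit (a seeded subsample beyond the cap; bounds fit time on
#'   very large pools).
#' @param gd_queries cap on the labeled candidates used as gradient-descent
#'   training rows; the purity features of these queries are still computed
#'   against the *full* exemplar memory, so the memory keeps growing with
#'   the training set while fit time stays bounded.
#' @param use_shape_kernel also compute a purity estimate in z-scored shape
#'   feature space (off by default; the appearance-memory estimate subsumes
#'   it at half the cost).
#' @param kernel_bandwidth Epanechnikov kernel bandwidth, in z-scored
#'   feature units, of the shape-feature purity estimate.
#' @param crop_bandwidth kernel bandwidth of the appearance-memory purity
#'   estimate, in normalized-embedding distance units.
#' @param crop_grid side of the square appearance embedding (grid^2
#'   dimensions).
#' @return a `detector_config` object.
#' @export
detector_config <- function(tau_probs = c(0.85, 0.88, 0.90, 0.915,
                                          0.925, 0.935),
                            tau_patches = NULL,
                            min_area = 6, max_area = 2500,
                            label_iou = 0.5,
                            gd_iters = 200, learning_rate = 0.4, l2 = 1e-4,
                            max_exemplars = 24000,
                            max_fit_patches = 3300,
                            gd_queries = 8000,
                            use_shape_kernel = FALSE,
                            kernel_bandwidth = 1.0,
                            crop_bandwidth = 0.6, crop_grid = 6L) {
  structure(list(tau_probs = tau_probs, tau_patches = tau_patches,
                 min_area = min_area, max_area = max_area,
                 label_iou = label_iou, gd_iters = gd_iters,
                 learning_rate = learning_rate, l2 = l2,
                 max_exemplars = max_exemplars,
                 max_fit_patches = max_fit_patches,
                 gd_queries = gd_queries,
                 use_shape_kernel = isTRUE(use_shape_kernel),
                 kernel_bandwidth = kernel_bandwidth,
                 crop_bandwidth = crop_bandwidth,
                 crop_grid = as.integer(crop_grid)),
            class = "detector_config")
}

# Kernel estimate of the positive fraction around each query row, against
# the stored exemplars (rows of ex_z, labels ex_y), Epanechnikov kernel
# k(d) = max(1 - d^2/h^2, 0) in the given feature space (compact support:
# only exemplars within distance h vote, so estimates genuinely sharpen as
# the memory fills). loo subtracts each query's own contribution (used at
# fit time when the queries are the exemplars' source). Queries with no
# in-range exemplar fall back to the training prior.
kernel_purity <- function(query_z, ex_z, ex_y, h, loo = FALSE,
                          self_idx = NULL, prior = 0.5) {
  nq <- nrow(query_z)
  if (nq == 0) return(numeric(0))
  ne <- nrow(ex_z)
  out <- numeric(nq)
  qn <- rowSums(query_z^2)
  en <- rowSums(ex_z^2)
  h2 <- h^2
  ecol <- (1 - en / h2) # per-exemplar additive term of the kernel
  chunk <- max(1L, floor(2e7 / ne))
  i <- 1L
  while (i <= nq) {
    j <- min(nq, i + chunk - 1L)
    # k = 1 - (qn + en - 2 q.e)/h^2, built with minimal temporaries
    k <- tcrossprod(query_z[i:j, , drop = FALSE] * (2 / h2), ex_z)
    k <- k + rep(ecol, each = j - i + 1L)
    k <- k - qn[i:j] / h2
    k[k < 0] <- 0
    num <- drop(k %*% ex_y)
    den <- rowSums(k)
    if (loo) {
      sl <- self_idx[i:j]
      has <- !is.na(sl)
      num[has] <- num[has] - ex_y[sl[has]]
      den[has] <- den[has] - 1
    }
    out[i:j] <- ifelse(den > 1e-8, num / den, prior)
    i <- j + 1L
  }
  out
}

# Fixed-size appearance embedding of a candidate: the candidate's region of
# the (vegetation-scaled) index field, block-averaged to grid x grid cells,
# centered and L2-normalized. Removes brightness/contrast; keeps shape.
crop_embed <- function(exg, cand, veg_scale, grid = 8L) {
  embed_num(exg, veg_scale, cand$min_x, cand$min_y, cand$max_x, cand$max_y,
            grid)
}

embed_num <- function(exg, veg_scale, mnx, mny, mxx, mxy, grid = 8L) {
  h <- nrow(exg); w <- ncol(exg)
  r0 <- max(1L, floor(mny) + 1L); r1 <- min(h, max(r0, ceiling(mxy)))
  c0 <- max(1L, floor(mnx) + 1L); c1 <- min(w, max(c0, ceiling(mxx)))
  crop <- exg[r0:r1, c0:c1, drop = FALSE] / veg_scale
  ri <- pmin(nrow(crop), floor(((seq_len(grid)) - 0.5) * nrow(crop) / grid) + 1L)
  ci <- pmin(ncol(crop), floor(((seq_len(grid)) - 0.5) * ncol(crop) / grid) + 1L)
  v <- as.numeric(crop[ri, ci])
  v <- v - mean(v)
  n2 <- sqrt(sum(v^2))
  if (n2 > 1e-8) v / n2 else v
}

# Greedy one-to-one matching by descending IoU; returns the matched pairs.
greedy_iou_match <- function(a, b, iou_min = 0.5) {
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(data.frame(a = integer(), b = integer()))
  }
  m <- iou_matrix(a, b)
  pairs <- data.frame(a = integer(), b = integer())
  repeat {
    j <- which.max(m)
    if (m[j] < iou_min) break
    ai <- ((j - 1) %% nrow(m)) + 1
    bi <- ((j - 1) %/% nrow(m)) + 1
    pairs <- rbind(pairs, data.frame(a = ai, b = bi))
    m[ai, ] <- -1
    m[, bi] <- -1
  }
  pairs
}

feat_names <- c("area", "aspect", "fill", "exg_mean", "exg_sd",
                "contrast", "elongation")

#' Fit the reference detector
#'
#' A deliberately simple, CPU-trainable, label-driven detector standing in
#' for a deep single-stage model, so that training-set size, diversity, and
#' annotation-quality effects can be exercised at desk scale:
#'
#' 1. The vegetation threshold `tau` is chosen by grid search over quantiles
#'    of the pooled excess-green distribution, maximizing proposal-stage F1
#'    against the training annotations (IoU >= 0.5) on a seeded subsample of
#'    patches.
#' 2. Candidates proposed at `tau` on every training patch are labeled
#'    positive iff they reach IoU >= `label_iou` with an annotation, and a
#'    logistic score model is fit by full-batch gradient descent (fixed
#'    iterations and learning rate, seeded initialization) over
#'    [candidate_features()] plus a kernel-purity feature: the
#'    Gaussian-kernel-weighted fraction of positives among stored training
#'    exemplars near the candidate in feature space (leave-one-out during
#'    fitting). The exemplar memory and the size-scaled threshold subsample
#'    are the detector's data-hungry components — both genuinely improve
#'    with more training patches, which is what makes training-set size
#'    matter for this otherwise low-capacity model.
#' 3. Per-side size offsets (mean signed margin between matched proposals
#'    and their annotations) are learned and added to predicted boxes, so
#'    systematically loose training boxes produce systematically inflated
#'    predictions rather than being absorbed.
#'
#' Deterministic given `seed`. If the training pool contains no annotations
#' at all, fitting fails; if annotations exist but no candidate matches one,
#' a degenerate always-reject model is returned.
#'
#' @param patches list of training `patch_record`s (pixels + annotations).
#' @param config a [detector_config()].
#' @param seed RNG seed for the subsample and the weight initialization.
#' @return an `exg_detector_model`.
#' @export
fit_exg_detector <- function(patches, config = detector_config(), seed = 1) {
  if (length(patches) < 1) stop("need at least one training patch")
  n_anno <- sum(vapply(patches, function(p) nrow(p$boxes), integer(1)))
  if (n_anno == 0) {
    stop("training pool contains no annotations; cannot label candidates")
  }
  n <- length(patches)
  m_tau <- config$tau_patches
  if (is.null(m_tau)) m_tau <- min(max(ceiling(n / 8), 12), 400)
  sub <- withr::with_seed(derive_seed(seed, "tau_subsample"), {
    sample.int(n, min(m_tau, n))
  })
  sub_exg <- lapply(patches[sub], function(p) exg_index(p$pixels))
  pooled <- unlist(lapply(sub_exg, function(e) e[seq(1, length(e), by = 7)]))
  taus <- unique(stats::quantile(pooled, probs = config$tau_probs,
                                 names = FALSE))
  best_tau <- taus[1]; best_f1 <- -1
  for (tau in taus) {
    tp <- 0; np <- 0; na <- 0
    for (k in seq_along(sub)) {
      cand <- propose_candidates(sub_exg[[k]], tau,
                                 config$min_area, config$max_area)
      anno <- patches[[sub[k]]]$boxes
      tp <- tp + nrow(greedy_iou_match(cand, anno, 0.5))
      np <- np + nrow(cand); na <- na + nrow(anno)
    }
    f1 <- if (np + na > 0) 2 * tp / (np + na) else 0
    if (f1 > best_f1 + 1e-12) { best_f1 <- f1; best_tau <- tau }
  }
  # final pass: features, labels, embeddings, and size offsets
  fit_patches <- patches
  if (length(fit_patches) > config$max_fit_patches) {
    keep_p <- withr::with_seed(derive_seed(seed, "fit_patches"), {
      sort(sample.int(length(fit_patches), config$max_fit_patches))
    })
    fit_patches <- fit_patches[keep_p]
  }
  feats <- list(); labels <- list(); margins <- list(); embs <- list()
  g2 <- config$crop_grid^2
  for (p in fit_patches) {
    e <- exg_index(p$pixels)
    cand <- propose_candidates(e, best_tau, config$min_area, config$max_area)
    if (nrow(cand) == 0) next
    vs <- patch_veg_scale(e)
    mnx <- cand$min_x; mny <- cand$min_y; mxx <- cand$max_x; mxy <- cand$max_y
    fx <- t(vapply(seq_len(nrow(cand)), function(i) {
      features_num(e, vs, best_tau, mnx[i], mny[i], mxx[i], mxy[i])
    }, numeric(7)))
    ex <- t(vapply(seq_len(nrow(cand)), function(i) {
      embed_num(e, vs, mnx[i], mny[i], mxx[i], mxy[i], config$crop_grid)
    }, numeric(g2)))
    anno <- p$boxes
    if (nrow(anno) > 0) {
      mIoU <- apply(iou_matrix(cand, anno), 1, max)
      lab <- as.numeric(mIoU >= config$label_iou)
      pr <- greedy_iou_match(cand, anno, config$label_iou)
      if (nrow(pr) > 0) {
        margins[[length(margins) + 1]] <- cbind(
          anno$min_x[pr$b] - cand$min_x[pr$a],
          anno$min_y[pr$b] - cand$min_y[pr$a],
          anno$max_x[pr$b] - cand$max_x[pr$a],
          anno$max_y[pr$b] - cand$max_y[pr$a])
      }
    } else {
      lab <- rep(0, nrow(cand))
    }
    feats[[length(feats) + 1]] <- fx
    labels[[length(labels) + 1]] <- lab
    embs[[length(embs) + 1]] <- ex
  }
  X <- do.call(rbind, feats)
  Emb <- do.call(rbind, embs)
  y <- unlist(labels)
  model_meta <- list(seed = seed, n_patches = length(patches),
                     n_candidates = length(y), tau_f1 = best_f1)
  if (is.null(X) || sum(y) == 0) {
    # annotations exist but nothing matched: always-reject fallback
    n_w <- 1L + 7L + as.integer(isTRUE(config$use_shape_kernel)) + 1L
    return(structure(list(tau = best_tau, feat_mean = rep(0, 7),
                          feat_sd = rep(1, 7),
                          use_shape_kernel = isTRUE(config$use_shape_kernel),
                          nw_mean = 0, nw_sd = 1,
                          cnw_mean = 0, cnw_sd = 1,
                          exemplars = matrix(0, 0, 7),
                          crop_exemplars = matrix(0, 0, g2),
                          exemplar_labels = numeric(0), prior = 0,
                          bandwidth = config$kernel_bandwidth,
                          crop_bandwidth = config$crop_bandwidth,
                          crop_grid = config$crop_grid,
                          weights = c(-10, rep(0, n_w - 1L)),
                          offsets = rep(0, 4),
                          min_area = config$min_area,
                          max_area = config$max_area,
                          degenerate = TRUE, meta = model_meta,
                          version = "2"),
                     class = "exg_detector_model"))
  }
  mu <- colMeans(X)
  sdv <- pmax(apply(X, 2, stats::sd), 1e-6)
  Z7 <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  n_cand <- nrow(Z7)
  # exemplar memory behind the two kernel-purity features: all training
  # candidates (up to the cap) - the memory grows with the training set
  if (n_cand > config$max_exemplars) {
    ex_idx <- withr::with_seed(derive_seed(seed, "exemplars"), {
      sort(sample.int(n_cand, config$max_exemplars))
    })
  } else {
    ex_idx <- seq_len(n_cand)
  }
  ex_z <- Z7[ex_idx, , drop = FALSE]
  ex_emb <- Emb[ex_idx, , drop = FALSE]
  ex_y <- y[ex_idx]
  prior <- mean(y)
  # gradient-descent rows: a (seeded) subsample of candidates, scored
  # against the full memory with leave-one-out
  if (n_cand > config$gd_queries) {
    q_idx <- withr::with_seed(derive_seed(seed, "gd_queries"), {
      sort(sample.int(n_cand, config$gd_queries))
    })
  } else {
    q_idx <- seq_len(n_cand)
  }
  self_idx <- match(q_idx, ex_idx)
  yq <- y[q_idx]
  use_shape <- isTRUE(config$use_shape_kernel)
  if (use_shape) {
    nw <- kernel_purity(Z7[q_idx, , drop = FALSE], ex_z, ex_y,
                        config$kernel_bandwidth,
                        loo = TRUE, self_idx = self_idx, prior = prior)
    nw_mean <- mean(nw); nw_sd <- max(stats::sd(nw), 1e-6)
  } else {
    nw <- NULL; nw_mean <- 0; nw_sd <- 1
  }
  cnw <- kernel_purity(Emb[q_idx, , drop = FALSE], ex_emb, ex_y,
                       config$crop_bandwidth,
                       loo = TRUE, self_idx = self_idx, prior = prior)
  cnw_mean <- mean(cnw); cnw_sd <- max(stats::sd(cnw), 1e-6)
  Z <- cbind(1, Z7[q_idx, , drop = FALSE],
             if (use_shape) (nw - nw_mean) / nw_sd,
             (cnw - cnw_mean) / cnw_sd)
  w <- withr::with_seed(derive_seed(seed, "gd_init"), {
    stats::rnorm(ncol(Z), 0, 0.01)
  })
  lr <- config$learning_rate
  for (it in seq_len(config$gd_iters)) {
    pr <- 1 / (1 + exp(-drop(Z %*% w)))
    grad <- drop(crossprod(Z, yq - pr)) / length(yq) - config$l2 * w
    w <- w + lr * grad
  }
  offsets <- if (length(margins) > 0) colMeans(do.call(rbind, margins))
             else rep(0, 4)
  structure(list(tau = best_tau, feat_mean = unname(mu),
                 feat_sd = unname(sdv), use_shape_kernel = use_shape,
                 nw_mean = nw_mean, nw_sd = nw_sd,
                 cnw_mean = cnw_mean, cnw_sd = cnw_sd,
                 exemplars = if (use_shape) unname(ex_z)
                             else matrix(0, 0, 7),
                 crop_exemplars = unname(ex_emb),
                 exemplar_labels = ex_y,
                 prior = prior, bandwidth = config$kernel_bandwidth,
                 crop_bandwidth = config$crop_bandwidth,
                 crop_grid = config$crop_grid,
                 weights = unname(w), offsets = unname(offsets),
                 min_area = config$min_area, max_area = config$max_area,
                 degenerate = FALSE, meta = model_meta, version = "2"),
            class = "exg_detector_model")
}

#' Predict seedling boxes on one patch
#'
#' Proposes candidates at the model's vegetation threshold, scores each with
#' the logistic model (confidence = sigmoid score, in `[0, 1]`), applies the
#' learned per-side size offsets, and clips to the patch. Deterministic
#' given the model.
#'
#' @param model an `exg_detector_model`.
#' @param pixels patch pixel array `(s, s, 3)`.
#' @return a scored box table in patch-local coordinates.
#' @export
predict_exg_detector <- function(model, pixels) {
  e <- exg_index(pixels)
  cand <- propose_candidates(e, model$tau, model$min_area, model$max_area)
  if (nrow(cand) == 0) return(boxes())
  vs <- patch_veg_scale(e)
  g <- model$crop_grid
  mnx <- cand$min_x; mny <- cand$min_y; mxx <- cand$max_x; mxy <- cand$max_y
  X <- t(vapply(seq_len(nrow(cand)), function(i) {
    features_num(e, vs, model$tau, mnx[i], mny[i], mxx[i], mxy[i])
  }, numeric(7)))
  Emb <- t(vapply(seq_len(nrow(cand)), function(i) {
    embed_num(e, vs, mnx[i], mny[i], mxx[i], mxy[i], g)
  }, numeric(g^2)))
  Z7 <- sweep(sweep(X, 2, model$feat_mean), 2, model$feat_sd, "/")
  cex <- model$crop_exemplars
  if (!is.matrix(cex)) cex <- matrix(as.numeric(cex), ncol = g^2)
  use_shape <- isTRUE(model$use_shape_kernel)
  cnw <- if (nrow(cex) > 0) {
    kernel_purity(Emb, cex, model$exemplar_labels,
                  model$crop_bandwidth, prior = model$prior)
  } else {
    rep(model$prior, nrow(Z7))
  }
  nw_col <- NULL
  if (use_shape) {
    ex <- model$exemplars
    if (!is.matrix(ex)) ex <- matrix(as.numeric(ex), ncol = 7)
    nw <- if (nrow(ex) > 0) {
      kernel_purity(Z7, ex, model$exemplar_labels, model$bandwidth,
                    prior = model$prior)
    } else {
      rep(model$prior, nrow(Z7))
    }
    nw_col <- (nw - model$nw_mean) / model$nw_sd
  }
  Z <- cbind(1, Z7, nw_col, (cnw - model$cnw_mean) / model$cnw_sd)
  conf <- 1 / (1 + exp(-drop(Z %*% model$weights)))
  s <- c(nrow(e), ncol(e))
  out <- data.frame(
    min_x = pmax(0, cand$min_x + model$offsets[1]),
    min_y = pmax(0, cand$min_y + model$offsets[2]),
    max_x = pmin(s[2], cand$max_x + model$offsets[3]),
    max_y = pmin(s[1], cand$max_y + model$offsets[4]),
    confidence = conf)
  out <- out[out$max_x > out$min_x & out$max_y > out$min_y, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detector contracts
#'
#' A detector is a list with a `name`, a `fit(patches, seed)` function
#' returning a model, and a `predict(model, pixels)` function returning a
#' scored box table with confidences in `[0, 1]` and boxes within the patch.
#' `reference_detector()` wraps the excess-green reference implementation;
#' `mock_detector()` is a trivial training-free detector used to test
#' contract compliance and pipeline plumbing independently of the reference
#' implementation.
#'
#' @param config a [detector_config()] for the reference detector.
#' @return a `detector_contract` object.
#' @export
reference_detector <- function(config = detector_config()) {
  structure(list(
    name = "reference",
    fit = function(patches, seed = 1) fit_exg_detector(patches, config, seed),
    predict = function(model, pixels) predict_exg_detector(model, pixels)
  ), class = "detector_contract")
}

#' @rdname reference_detector
#' @param tau fixed vegetation threshold used by the mock detector.
#' @export
mock_detector <- function(tau = 0.25) {
  structure(list(
    name = "mock",
    fit = function(patches, seed = 1) list(tau = tau),
    predict = function(model, pixels) {
      cand <- propose_candidates(exg_index(pixels), model$tau, 2, 1e6)
      if (nrow(cand) == 0) return(boxes())
      data.frame(min_x = cand$min_x, min_y = cand$min_y,
                 max_x = cand$max_x, max_y = cand$max_y,
                 confidence = 0.9)
    }
  ), class = "detector_contract")
}

#' Serialize / restore a detector model
#'
#' Models are written as versioned JSON so they can be inspected and
#' round-tripped across sessions.
#'
#' @param model an `exg_detector_model`.
#' @param path file path.
#' @return `read_model` returns the restored model.
#' @export
write_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(m, class = "exg_detector_model")
}
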