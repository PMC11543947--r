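#' Parameter ranges for synthetic acquisition domains
#'
#' Every synthetic image set (= one simulated acquisition session) is
#' governed by a `domain_params` vector drawn uniformly from these ranges.
#' The `"train"` ranges define the training distribution; the `"ood"` ranges
#' are deliberately wider along the distribution-shift axes the benchmark
#' studies — object size, image sharpness (blur), occlusion (stubble),
#' distractor pressure (weeds), lighting, and sensor noise — so that
#' out-of-distribution sets are systematically harder than in-distribution
#' ones.
#'
#' All length units are pixels of the rendered image.
#'
#' @param shift `"train"` or `"ood"`.
#' @return named list of `c(lo, hi)` ranges.
#' @export
domain_ranges <- function(shift = c("train", "ood")) {
  shift <- match.arg(shift)
  if (shift == "train") {
    list(
      plant_rate    = c(18, 30),   # expected seedlings per image (Poisson)
      row_spacing   = c(22, 30),   # crop row pitch
      row_jitter    = c(1.5, 3),   # in-row placement sd
      cotyledon_len = c(5.5, 8.5), # mean cotyledon length
      cotyledon_sd  = c(0.3, 0.8),
      leaf_max      = c(0, 4),     # true leaves per seedling (upper bound)
      foliage_green = c(0.55, 0.75),
      foliage_rb    = c(0.16, 0.30), # red/blue level relative to green
      soil_bright   = c(0.35, 0.50),
      soil_rough    = c(0.02, 0.06),
      illumination  = c(0.85, 1.15),
      blur_sigma    = c(0.3, 0.9),
      noise_sd      = c(0.010, 0.030),
      weed_rate     = c(5, 16),
      weed_species  = c(0, 1),   # continuous proxy for the local weed flora
      weed_mimicry  = c(0, 1),   # how plant-like the local weeds are
      stubble_rate  = c(2, 6)
    )
  } else {
    list(
      plant_rate    = c(12, 40),
      row_spacing   = c(18, 36),
      row_jitter    = c(1, 5),
      cotyledon_len = c(4.5, 10.0),
      cotyledon_sd  = c(0.3, 1.0),
      leaf_max      = c(0, 4),
      foliage_green = c(0.45, 0.85),
      foliage_rb    = c(0.12, 0.36),
      soil_bright   = c(0.28, 0.58),
      soil_rough    = c(0.02, 0.10),
      illumination  = c(0.70, 1.30),
      blur_sigma    = c(0.3, 1.3),
      noise_sd      = c(0.010, 0.050),
      weed_rate     = c(3, 26),
      weed_species  = c(0, 1),
      weed_mimicry  = c(0, 1),
      stubble_rate  = c(2, 12)
    )
  }
}

#' Sample the generative parameters of one synthetic domain
#'
#' Each field is drawn independently and uniformly from its range;
#' `leaf_max` is rounded to an integer. Deterministic given `seed`.
#'
#' @param seed RNG seed for the draw.
#' @param ranges named list of `c(lo, hi)` ranges, as from [domain_ranges()].
#' @return a `domain_params` object (named list of scalars plus the seed).
#' @export
sample_domain_params <- function(seed, ranges = domain_ranges("train")) {
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2 || !is.numeric(r) || r[1] > r[2]) {
      stop("malformed range for field '", nm, "'")
    }
  }
  p <- withr::with_seed(seed, {
    vals <- lapply(ranges, function(r) stats::runif(1, r[1], r[2]))
    vals
  })
  p$leaf_max <- as.integer(round(p$leaf_max))
  p$seed <- seed
  structure(p, class = "domain_params")
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Linear pixel indices (into an h x w plane) of an ellipse with center
# (cx, cy), semi-axes (a, b), rotated by theta. Pixel centers are at
# (col - 0.5, row - 0.5).
ellipse_idx <- function(h, w, cx, cy, a, b, theta) {
  R <- max(a, b) + 1
  r0 <- max(1L, floor(cy - R) + 1L); r1 <- min(h, ceiling(cy + R))
  c0 <- max(1L, floor(cx - R) + 1L); c1 <- min(w, ceiling(cx + R))
  if (r0 > r1 || c0 > c1) return(integer())
  rows <- r0:r1; cols <- c0:c1
  x <- rep(cols - 0.5, each = length(rows)) - cx
  y <- rep(rows - 0.5, times = length(cols)) - cy
  u <- x * cos(theta) + y * sin(theta)
  v <- -x * sin(theta) + y * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  rr <- rep(rows, times = length(cols))[inside]
  cc <- rep(cols, each = length(rows))[inside]
  (cc - 1L) * h + rr
}

# Pixel indices of a thick line segment (stubble straw).
segment_idx <- function(h, w, x0, y0, angle, len, half_width) {
  n <- max(2L, ceiling(len / 0.4))
  t <- seq(-len / 2, len / 2, length.out = n)
  offs <- seq(-half_width, half_width, by = 0.4)
  dx <- cos(angle); dy <- sin(angle)
  px <- outer(t * dx, offs * -dy, `+`) + x0
  py <- outer(t * dy, offs * dx, `+`) + y0
  cc <- floor(px) + 1L; rr <- floor(py) + 1L
  ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
  unique((cc[ok] - 1L) * h + rr[ok])
}

paint_idx <- function(img, idx, color, jitter_sd = 0.02) {
  if (length(idx) == 0) return(img)
  hw <- dim(img)[1] * dim(img)[2]
  for (ch in 1:3) {
    img[idx + (ch - 1L) * hw] <-
      clamp01(color[ch] + stats::rnorm(length(idx), 0, jitter_sd))
  }
  img
}

# Draw one seedling: two opposed cotyledon ellipses about a small center
# disc, plus 0..leaf_max smaller leaf ellipses at random angles.
# Returns the pixel indices of the rendered plant.
# The linear scale is calibrated so that the orientation-averaged tight box
# of a leafless pair has mean side ~= 2 * len (the nominal tip-to-tip span):
# a box of a shape with extent E at uniform random orientation has mean
# side ~0.64 E + width terms, hence the 0.61 factor on the ellipse axes.
seedling_idx <- function(h, w, x, y, len, leaf_max) {
  theta <- stats::runif(1, 0, pi)
  a <- 0.61 * len
  b <- max(1.3, 0.40 * len)
  off <- a + 1.2
  e1 <- ellipse_idx(h, w, x + off * cos(theta), y + off * sin(theta),
                    a, b, theta)
  e2 <- ellipse_idx(h, w, x - off * cos(theta), y - off * sin(theta),
                    a, b, theta)
  disc <- ellipse_idx(h, w, x, y, max(1.5, 0.26 * len), max(1.5, 0.26 * len), 0)
  idx <- c(e1, e2, disc)
  # leaf habit is a domain trait: plants in one session share a growth
  # stage, so the per-plant leaf count varies only within leaf_max-2..leaf_max
  leaf_lo <- max(0L, leaf_max - 2L)
  k <- if (leaf_max > 0) {
    leaf_lo + sample.int(leaf_max - leaf_lo + 1L, 1L) - 1L
  } else 0L
  if (k > 0) {
    for (i in seq_len(k)) {
      ang <- stats::runif(1, 0, 2 * pi)
      d <- 0.43 * len
      idx <- c(idx, ellipse_idx(h, w, x + d * cos(ang), y + d * sin(ang),
                                0.37 * len, max(1.0, 0.22 * len), ang))
    }
  }
  unique(idx)
}

# Green distractors in the same color family as the crop, so only shape and
# context separate them. Two kinds: scruffy multi-lobe clusters, and
# "mimics" - two-lobed weeds that imitate a cotyledon pair with the wrong
# proportions (unequal lobes, a bent axis, an off-center joint). Mimics are
# the hard negatives of this benchmark: rejecting them requires a finely
# resolved decision boundary, which is what makes training-set size and
# coverage matter to downstream classifiers.
weed_idx <- function(h, w, x, y, size, mimic = FALSE, species = 0.5) {
  idx <- integer()
  if (mimic) {
    theta <- stats::runif(1, 0, pi)
    # the local flora sets the typical lobe proportions and axis bend:
    # different fields grow different-looking weeds, while any one field's
    # weeds look alike (narrow within-domain spread)
    bend_max <- 0.15 + 0.6 * species
    bend <- stats::runif(1, -bend_max, bend_max)
    rc <- 0.40 + 0.45 * species
    ratio <- stats::runif(1, rc - 0.07, rc + 0.07)
    a1 <- 0.61 * size; b1 <- max(1.1, 0.40 * size)
    a2 <- a1 * ratio; b2 <- max(1.0, b1 * ratio)
    off1 <- a1 + 1.0
    off2 <- a2 + stats::runif(1, 0.2, 2.0)
    idx <- c(
      ellipse_idx(h, w, x + off1 * cos(theta), y + off1 * sin(theta),
                  a1, b1, theta),
      ellipse_idx(h, w, x - off2 * cos(theta + bend),
                  y - off2 * sin(theta + bend), a2, b2, theta + bend))
    if (stats::runif(1) < 0.5) {
      idx <- c(idx, ellipse_idx(h, w, x, y, max(1.1, 0.14 * size),
                                max(1.1, 0.14 * size), 0))
    }
  } else {
    m <- sample(3:6, 1)
    for (i in seq_len(m)) {
      cx <- x + stats::rnorm(1, 0, size * 0.8)
      cy <- y + stats::rnorm(1, 0, size * 0.8)
      idx <- c(idx, ellipse_idx(h, w, cx, cy,
                                stats::runif(1, 0.5, 1.2) * size,
                                stats::runif(1, 0.2, 0.5) * size,
                                stats::runif(1, 0, pi)))
    }
  }
  unique(idx)
}

#' Render one synthetic aerial field image with ground-truth boxes
#'
#' Rendering pipeline: paint textured soil, draw under-layer stubble, draw
#' seedlings and weeds, draw over-layer stubble (the occluding half of the
#' straw), apply the multiplicative illumination scale, Gaussian blur, and
#' additive sensor noise. Each seedling's annotation is the tight bounding
#' box of its rendered pixels; a seedling is annotated iff at least 30% of
#' its pixels remain visible under the over-layer stubble. Weeds and stubble
#' are never annotated.
#'
#' @param params a [sample_domain_params()] result.
#' @param width,height image dimensions in pixels (at least ~3x the plant
#'   size; smaller than 32 px is rejected).
#' @param seed RNG seed; identical seeds reproduce bit-identical images.
#' @param image_id,domain_id identifiers stored on the record.
#' @return a `field_image`: list with `id`, `domain_id`, `width`, `height`,
#'   `pixels` (`height x width x 3` array in `[0, 1]`), `boxes`
#'   (annotations), and `meta` (placement bookkeeping).
#' @export
render_field_image <- function(params, width, height, seed,
                               image_id = "img", domain_id = NA_character_) {
  if (width < 32 || height < 32) stop("image dimensions too small")
  p <- params
  withr::with_seed(seed, {
    h <- as.integer(height); w <- as.integer(width)
    img <- array(0, dim = c(h, w, 3))
    # -- soil: brownish base plus low-frequency texture
    base <- c(p$soil_bright * 1.08, p$soil_bright * 0.95, p$soil_bright * 0.76)
    tex <- matrix(stats::rnorm(h * w), h, w)
    tex <- EBImage::gblur(tex, sigma = 2.5)
    tex <- tex / stats::sd(tex) * p$soil_rough
    for (ch in 1:3) img[, , ch] <- clamp01(base[ch] + tex)
    # -- stubble: pale straight straws; about half occlude the canopy layer
    n_st <- stats::rpois(1, p$stubble_rate)
    over_segments <- list()
    if (n_st > 0) {
      for (i in seq_len(n_st)) {
        sx <- stats::runif(1, 0, w); sy <- stats::runif(1, 0, h)
        ang <- stats::runif(1, 0, pi)
        len <- stats::runif(1, 0.25, 0.7) * w
        hw2 <- stats::runif(1, 0.5, 1.0)
        shade <- stats::runif(1, 0.75, 1.05)
        col <- c(0.78, 0.72, 0.55) * shade
        idx <- segment_idx(h, w, sx, sy, ang, len, hw2)
        if (stats::runif(1) < 0.5) {
          over_segments[[length(over_segments) + 1]] <-
            list(idx = idx, col = col)
        } else {
          img <- paint_idx(img, idx, col, jitter_sd = 0.015)
        }
      }
    }
    # -- seedlings on jittered rows
    phase <- stats::runif(1, 0, p$row_spacing)
    rows_x <- seq(phase, w, by = p$row_spacing)
    n_p <- stats::rpois(1, p$plant_rate)
    plant_px <- list()
    if (n_p > 0) {
      for (i in seq_len(n_p)) {
        rx <- rows_x[sample.int(length(rows_x), 1)]
        x <- rx + stats::rnorm(1, 0, p$row_jitter)
        y <- stats::runif(1, 0, h)
        len <- max(2.5, stats::rnorm(1, p$cotyledon_len, p$cotyledon_sd))
        idx <- seedling_idx(h, w, x, y, len, p$leaf_max)
        if (length(idx) == 0) next
        g <- clamp01(p$foliage_green + stats::rnorm(1, 0, 0.05))
        col <- c(p$foliage_rb * g * stats::runif(1, 0.85, 1.15), g,
                 p$foliage_rb * g * 0.8 * stats::runif(1, 0.85, 1.15))
        img <- paint_idx(img, idx, col)
        plant_px[[length(plant_px) + 1]] <- idx
      }
    }
    # -- weeds: never annotated
    n_w <- stats::rpois(1, p$weed_rate)
    if (n_w > 0) {
      mimic_frac <- 0.30 + 0.55 * p$weed_mimicry
      for (i in seq_len(n_w)) {
        x <- stats::runif(1, 0, w); y <- stats::runif(1, 0, h)
        mimic <- stats::runif(1) < mimic_frac
        size <- if (mimic) {
          p$cotyledon_len * stats::runif(1, 0.55, 1.0)
        } else {
          stats::runif(1, 2.2, 5.5)
        }
        idx <- weed_idx(h, w, x, y, size, mimic = mimic,
                        species = p$weed_species)
        g <- clamp01(p$foliage_green + stats::rnorm(1, 0, 0.06))
        col <- c(p$foliage_rb * g * stats::runif(1, 0.85, 1.15), g,
                 p$foliage_rb * g * 0.8 * stats::runif(1, 0.85, 1.15))
        img <- paint_idx(img, idx, col)
      }
    }
    # -- over-layer stubble occludes the canopy
    over_idx <- integer()
    for (seg in over_segments) {
      img <- paint_idx(img, seg$idx, seg$col, jitter_sd = 0.015)
      over_idx <- c(over_idx, seg$idx)
    }
    over_idx <- unique(over_idx)
    # -- annotations: visibility rule, tight boxes from rendered pixels
    keep_box <- function(idx) {
      vis <- if (length(over_idx) == 0) 1 else
        1 - length(intersect(idx, over_idx)) / length(idx)
      if (vis < 0.3) return(NULL)
      rr <- ((idx - 1L) %% h) + 1L
      cc <- ((idx - 1L) %/% h) + 1L
      c(min(cc) - 1, min(rr) - 1, max(cc), max(rr))
    }
    bx <- Filter(Negate(is.null), lapply(plant_px, keep_box))
    anno <- if (length(bx) > 0) {
      mb <- do.call(rbind, bx)
      data.frame(min_x = mb[, 1], min_y = mb[, 2],
                 max_x = mb[, 3], max_y = mb[, 4], confidence = NA_real_)
    } else {
      boxes()
    }
    # -- illumination, blur, sensor noise
    img <- img * p$illumination
    if (p$blur_sigma > 0.05) {
      for (ch in 1:3) img[, , ch] <- EBImage::gblur(img[, , ch],
                                                    sigma = p$blur_sigma)
    }
    if (p$noise_sd > 0) {
      img <- img + stats::rnorm(length(img), 0, p$noise_sd)
    }
    img <- clamp01(img)
    structure(list(id = image_id, domain_id = domain_id, set_id = NULL,
                   width = w, height = h, pixels = img, boxes = anno,
                   meta = list(n_placed = length(plant_px),
                               n_stubble = n_st, n_weeds = n_w)),
              class = "field_image")
  })
}

#' Generate one image set (one simulated acquisition session)
#'
#' All images share the set's `domain_params`; each image uses a per-image
#' sub-seed derived from the set seed.
#'
#' @param params a `domain_params` object.
#' @param n_images number of images (at least 1).
#' @param width,height image dimensions.
#' @param seed set-level seed.
#' @param set_id identifier of the set.
#' @param role one of `"train"`, `"id_test"`, `"ood_test"`.
#' @return an `image_set`: list with `id`, `role`, `params`, `seed`, and
#'   `images` (list of `field_image`).
#' @export
generate_image_set <- function(params, n_images, width, height, seed,
                               set_id, role = "train") {
  stopifnot(n_images >= 1)
  role <- match.arg(role, c("train", "id_test", "ood_test"))
  images <- lapply(seq_len(n_images), function(i) {
    im <- render_field_image(params, width, height,
                             seed = derive_seed(seed, "image", i),
                             image_id = sprintf("%s_img%03d", set_id, i),
                             domain_id = set_id)
    im$set_id <- set_id
    im
  })
  structure(list(id = set_id, role = role, params = params, seed = seed,
                 width = width, height = height, images = images),
            class = "image_set")
}

#' Build the full synthetic benchmark (train / ID-test / OOD-test layout)
#'
#' Mirrors the structure of a multi-session field dataset: `k_train`
#' training domains, each contributing a training image set and a held-out
#' in-distribution test set drawn from the same domain parameters (same
#' acquisition session), plus `k_ood` freshly sampled domains for
#' out-of-distribution testing. OOD domain parameters are drawn from the
#' wider [domain_ranges()]`("ood")` ranges.
#'
#' Desk-scale defaults (8 + 8 domains, 192 px images, 96 px patches, 100
#' training images per set giving a 3,200-patch training pool) keep full
#' experiment sweeps in minutes on one CPU while preserving the layout of
#' the full-scale dataset (27 + 27 sets of 416 px patches).
#'
#' @param k_train,k_ood number of training and OOD domains.
#' @param n_train_images,n_id_images,n_ood_images images per set by role.
#' @param width,height image dimensions.
#' @param patch_size patch side used downstream.
#' @param seed master seed.
#' @param train_ranges,ood_ranges domain parameter ranges.
#' @return a `field_benchmark`: list with `train_sets`, `id_test_sets`,
#'   `ood_test_sets`, dimensions, `patch_size`, and `seed`.
#' @export
build_benchmark <- function(k_train = 8, k_ood = 8,
                            n_train_images = 100, n_id_images = 3,
                            n_ood_images = 6,
                            width = 192, height = 192, patch_size = 96,
                            seed = 1,
                            train_ranges = domain_ranges("train"),
                            ood_ranges = domain_ranges("ood")) {
  stopifnot(k_train >= 1, k_ood >= 1)
  train_sets <- list(); id_sets <- list()
  for (i in seq_len(k_train)) {
    par <- sample_domain_params(derive_seed(seed, "train_dom", i),
                                train_ranges)
    train_sets[[i]] <- generate_image_set(
      par, n_train_images, width, height,
      seed = derive_seed(seed, "train_imgs", i),
      set_id = sprintf("train%02d", i), role = "train")
    id_sets[[i]] <- generate_image_set(
      par, n_id_images, width, height,
      seed = derive_seed(seed, "id_imgs", i),
      set_id = sprintf("idtest%02d", i), role = "id_test")
  }
  ood_sets <- list()
  for (i in seq_len(k_ood)) {
    par <- sample_domain_params(derive_seed(seed, "ood_dom", i), ood_ranges)
    ood_sets[[i]] <- generate_image_set(
      par, n_ood_images, width, height,
      seed = derive_seed(seed, "ood_imgs", i),
      set_id = sprintf("oodtest%02d", i), role = "ood_test")
  }
  structure(list(train_sets = train_sets, id_test_sets = id_sets,
                 ood_test_sets = ood_sets,
                 width = width, height = height, patch_size = patch_size,
                 seed = seed),
            class = "field_benchmark")
}
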