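#' Annotation-noise configuration
#'
#' Bundles the two noise models applied to training annotations: box
#' dilation (loose labeling), bounded by `dilation_max` pixels per side, and
#' box removal (missed labeling) with probability `removal_prob` per box.
#' The study protocol varies one noise type at a time; configuring both at
#' once is allowed for exploration but flagged with a warning when applied.
#'
#' @param dilation_max nonnegative integer `N`: each box side is moved
#'   outward by an independent draw from the discrete uniform on `{0, ..., N}`.
#' @param removal_prob probability `P` in `[0, 1]` of deleting each box.
#' @param seed RNG seed making the corruption reproducible.
#' @return a `noise_config` object.
#' @export
noise_config <- function(dilation_max = 0, removal_prob = 0, seed = 1) {
  if (dilation_max < 0) stop("dilation_max must be nonnegative")
  if (removal_prob < 0 || removal_prob > 1) {
    stop("removal_prob must be in [0, 1]")
  }
  structure(list(dilation_max = as.integer(dilation_max),
                 removal_prob = removal_prob, seed = seed),
            class = "noise_config")
}

#' Dilate annotation boxes (loose-labeling noise)
#'
#' For each box, four independent draws `d1..d4` from the discrete uniform
#' on `{0, ..., n_max}` are taken in the fixed order (min_x, min_y, max_x,
#' max_y); the minimum coordinates are decreased and the maximum coordinates
#' increased by their draws, and the result is clipped to
#' `[0, width] x [0, height]`. With `n_max = 0` the annotations are returned
#' unchanged (and no random draws are consumed). Draws come from the current
#' RNG stream; seed at the call site for reproducibility.
#'
#' @param b a box table.
#' @param n_max maximum expansion per side, in pixels.
#' @param bounds numeric `(width, height)` of the enclosing image or patch.
#' @return the dilated box table (same row count and order).
#' @export
dilate_boxes <- function(b, n_max, bounds) {
  if (n_max < 0) stop("n_max must be nonnegative")
  validate_boxes(b)
  if (n_max == 0 || nrow(b) == 0) return(b)
  n <- nrow(b)
  # per-box draws in fixed order: min_x, min_y, max_x, max_y
  d <- matrix(sample.int(n_max + 1L, 4L * n, replace = TRUE) - 1L,
              nrow = n, ncol = 4L, byrow = TRUE)
  out <- data.frame(
    min_x = pmax(0, b$min_x - d[, 1]),
    min_y = pmax(0, b$min_y - d[, 2]),
    max_x = pmin(bounds[1], b$max_x + d[, 3]),
    max_y = pmin(bounds[2], b$max_y + d[, 4]),
    confidence = b$confidence
  )
  out
}

#' Remove annotation boxes at random (missed-labeling noise)
#'
#' Each box is independently retained with probability `1 - p`; surviving
#' boxes keep their geometry and relative order. Draws come from the current
#' RNG stream.
#'
#' @param b a box table.
#' @param p removal probability in `[0, 1]`.
#' @return the surviving boxes.
#' @export
drop_boxes <- function(b, p) {
  if (p < 0 || p > 1) stop("p must be in [0, 1]")
  validate_boxes(b)
  if (nrow(b) == 0) return(b)
  keep <- stats::runif(nrow(b)) >= p
  out <- b[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Corrupt the annotations of a patch pool
#'
#' Applies the configured noise to every patch's annotations, before any
#' training-set subsampling (matching the protocol: noise first, then
#' sampling without replacement). Pixel data are untouched. The entire
#' corruption is driven by `cfg$seed`, so the same configuration always
#' produces the same corrupted pool.
#'
#' @param patches a list of `patch_record`s.
#' @param cfg a [noise_config()].
#' @return the corrupted patch list.
#' @export
corrupt_dataset <- function(patches, cfg) {
  stopifnot(inherits(cfg, "noise_config"))
  if (cfg$dilation_max > 0 && cfg$removal_prob > 0) {
    warning("both dilation and removal noise active; the study protocol ",
            "varies one noise type at a time")
  }
  withr::with_seed(cfg$seed, {
    lapply(patches, function(p) {
      b <- p$boxes
      if (cfg$dilation_max > 0) {
        b <- dilate_boxes(b, cfg$dilation_max,
                          bounds = c(p$patch_size, p$patch_size))
      }
      if (cfg$removal_prob > 0) {
        b <- drop_boxes(b, cfg$removal_prob)
      }
      p$boxes <- b
      p
    })
  })
}
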