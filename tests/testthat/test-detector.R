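test_that("excess-green index hits its reference values", {
  px <- array(0, c(2, 2, 3))
  px[1, 1, ] <- c(0, 1, 0)          # pure green
  px[1, 2, ] <- c(1/3, 1/3, 1/3)    # gray
  px[2, 1, ] <- c(1, 0, 0)          # pure red
  e <- exg_index(px)
  expect_equal(e[1, 1], 2)
  expect_equal(e[1, 2], 0)
  expect_equal(e[2, 1], -1)
  expect_equal(e[2, 2], 0)          # black: sum 0 -> 0 by convention
})

test_that("candidate proposal finds blobs and applies the opening", {
  soil <- flat_patch(64)
  expect_equal(nrow(propose_candidates(exg_index(soil), 0.2)), 0)

  px <- soil
  px <- paint_rect(px, 5, 5, 12, 12)
  px <- paint_rect(px, 30, 8, 40, 16)
  px <- paint_rect(px, 10, 40, 22, 52)
  cand <- propose_candidates(exg_index(px), 0.2)
  expect_equal(nrow(cand), 3)
  got <- cand[order(cand$min_x), ]
  expect_equal(got$min_x, c(5, 10, 30))
  expect_equal(got$max_x, c(12, 22, 40))
  expect_equal(got$min_y, c(5, 40, 8))
  expect_equal(got$max_y, c(12, 52, 16))

  # two blobs joined by a 1-pixel bridge: the 3x3 opening removes the bridge
  px2 <- soil
  px2 <- paint_rect(px2, 5, 5, 13, 13)
  px2 <- paint_rect(px2, 20, 5, 28, 13)
  px2 <- paint_rect(px2, 13, 8, 20, 9) # 1-px-high bridge
  expect_equal(nrow(propose_candidates(exg_index(px2), 0.2)), 2)

  # without the bridge removal the same scene would be a single component
  lab <- EBImage::bwlabel(exg_index(px2) > 0.2)
  expect_equal(max(lab), 1)
})

test_that("the 3x3 opening matches a brute-force morphology oracle", {
  brute_open <- function(m) {
    n <- nrow(m); k <- ncol(m)
    pad <- matrix(FALSE, n + 4, k + 4); pad[3:(n + 2), 3:(k + 2)] <- m
    er <- matrix(FALSE, n + 4, k + 4)
    for (r in 2:(n + 3)) for (cc in 2:(k + 3)) {
      er[r, cc] <- all(pad[(r - 1):(r + 1), (cc - 1):(cc + 1)])
    }
    di <- matrix(FALSE, n + 4, k + 4)
    for (r in 2:(n + 3)) for (cc in 2:(k + 3)) {
      di[r, cc] <- any(er[(r - 1):(r + 1), (cc - 1):(cc + 1)])
    }
    di[3:(n + 2), 3:(k + 2)]
  }
  withr::with_seed(6, {
    for (i in 1:5) {
      m <- matrix(runif(30 * 30) > 0.7, 30, 30)
      expect_identical(seedlingbench:::binary_open3(m), brute_open(m))
    }
  })
})

test_that("candidate features have fixed length and geometric meaning", {
  px <- flat_patch(64)
  px <- paint_rect(px, 10, 10, 26, 26) # square solid blob
  cand <- propose_candidates(exg_index(px), 0.2)
  f <- candidate_features(px, cand[1, ], 0.2)
  expect_length(f, 7)
  expect_equal(unname(f["aspect"]), 1.0)
  expect_equal(unname(f["fill"]), 1.0)
  expect_equal(unname(f["area"]), log(256))
  expect_gt(unname(f["contrast"]), 0.5)

  # disc: fill ratio approaches pi/4
  px2 <- flat_patch(64)
  e <- exg_index(px2)
  disc_px <- px2
  cx <- 32.5; cy <- 32.5; r <- 12
  for (row in 1:64) for (col in 1:64) {
    if ((row - cy)^2 + (col - cx)^2 <= r^2) {
      disc_px[row, col, ] <- c(0.1, 0.7, 0.1)
    }
  }
  cand2 <- propose_candidates(exg_index(disc_px), 0.2)
  f2 <- candidate_features(disc_px, cand2[1, ], 0.2)
  expect_equal(unname(f2["fill"]), pi / 4, tolerance = 0.05)
  expect_equal(unname(f2["elongation"]), 1.0, tolerance = 0.1)

  expect_identical(candidate_features(px, cand[1, ], 0.2),
                   candidate_features(px, cand[1, ], 0.2))
  expect_error(candidate_features(px, boxes(50, 50, 70, 70), 0.2),
               "outside the patch")
})

easy_patch_pool <- function(n_images = 16, seed = 1) {
  par <- easy_domain_params()
  tr <- generate_image_set(par, n_images, 192, 192, seed = seed,
                           set_id = "easy", role = "train")
  grid <- plan_grid(192, 192, 96, 0)
  unlist(lapply(tr$images, extract_patches, grid = grid), recursive = FALSE)
}

test_that("fitting is deterministic and needs annotations", {
  pool <- easy_patch_pool(6)
  m1 <- fit_exg_detector(pool, seed = 3)
  m2 <- fit_exg_detector(pool, seed = 3)
  expect_identical(m1, m2)
  m3 <- fit_exg_detector(pool, seed = 4)
  expect_false(identical(m1$weights, m3$weights))

  empty <- lapply(pool, function(p) { p$boxes <- boxes(); p })
  expect_error(fit_exg_detector(empty, seed = 1), "no annotations")
})

test_that("prediction is deterministic, bounded, and quiet on bare soil", {
  pool <- easy_patch_pool(10)
  model <- fit_exg_detector(pool, seed = 3)
  expect_equal(nrow(predict_exg_detector(model, flat_patch(96))), 0)
  p <- pool[[4]]
  out1 <- predict_exg_detector(model, p$pixels)
  out2 <- predict_exg_detector(model, p$pixels)
  expect_identical(out1, out2)
  if (nrow(out1) > 0) {
    expect_true(all(out1$confidence >= 0 & out1$confidence <= 1))
    expect_true(all(out1$min_x >= 0 & out1$max_x <= 96))
  }
})

test_that("the detector recalls most training annotations on easy patches", {
  # sparse stand: plant-plant overlap (the dominant, irreducible miss mode
  # at field densities) is essentially absent, isolating per-plant recall
  rng <- domain_ranges("train")
  rng$plant_rate <- c(7, 7); rng$weed_rate <- c(0, 0)
  rng$stubble_rate <- c(0, 0); rng$blur_sigma <- c(0.3, 0.4)
  rng$leaf_max <- c(2, 2); rng$noise_sd <- c(0.010, 0.015)
  rng$cotyledon_len <- c(6.5, 7.5)
  par <- sample_domain_params(42, rng)
  tr <- generate_image_set(par, 16, 192, 192, seed = 1, set_id = "sparse",
                           role = "train")
  grid <- plan_grid(192, 192, 96, 0)
  pool <- unlist(lapply(tr$images, extract_patches, grid = grid),
                 recursive = FALSE)
  model <- fit_exg_detector(pool, seed = 3)
  tp <- 0; na <- 0
  for (p in pool) {
    if (nrow(p$boxes) == 0) next
    pred <- predict_exg_detector(model, p$pixels)
    pred <- pred[pred$confidence > 0.5, , drop = FALSE]
    m <- match_detections(pred, p$boxes)
    tp <- tp + m$tp; na <- na + nrow(p$boxes)
  }
  expect_gte(tp / na, 0.8)
})

test_that("easy single-domain held-out accuracy clears the floor", {
  par <- easy_domain_params()
  pool <- easy_patch_pool(20)
  te <- generate_image_set(par, 5, 192, 192, seed = 77, set_id = "easy_te",
                           role = "id_test")
  det <- reference_detector()
  model <- det$fit(pool, seed = 3)
  ev <- evaluate_sets(det, model, list(te), 96)
  expect_gte(mean(ev$accuracy), 0.7)
})

test_that("dilation-corrupted training labels inflate predicted boxes", {
  pool <- easy_patch_pool(14)
  det <- reference_detector()
  clean <- det$fit(pool, seed = 3)
  dirty <- det$fit(corrupt_dataset(pool, noise_config(6, 0, seed = 9)),
                   seed = 3)
  # learned size offsets point outward under dilation noise
  expect_true(dirty$offsets[1] < clean$offsets[1])
  expect_true(dirty$offsets[3] > clean$offsets[3])
  par <- easy_domain_params()
  im <- render_field_image(par, 192, 192, seed = 55)
  pc <- predict_image(det, clean, im$pixels, 96)
  pd <- predict_image(det, dirty, im$pixels, 96)
  pc <- pc[pc$confidence > 0.5, ]; pd <- pd[pd$confidence > 0.5, ]
  expect_gt(mean(box_area(pd)), mean(box_area(pc)))
  expect_gt(mean(box_area(pd)), mean(box_area(im$boxes)))
})

test_that("any detector honoring the contract runs through the pipeline", {
  det <- mock_detector()
  model <- det$fit(list(), seed = 1)
  par <- easy_domain_params()
  im <- render_field_image(par, 192, 192, seed = 12)
  out1 <- predict_image(det, model, im$pixels, 96)
  out2 <- predict_image(det, model, im$pixels, 96)
  expect_identical(out1, out2)
  validate_boxes(out1, require_conf = TRUE)
  expect_true(all(out1$confidence >= 0 & out1$confidence <= 1))
  expect_true(all(out1$min_x >= 0 & out1$max_x <= im$width))
  # the mock is a usable stand-in: it finds most of the easy vegetation
  m <- match_detections(out1, im$boxes, eval_thresholds(0.3, 0.5))
  expect_gt(m$tp / nrow(im$boxes), 0.5)
})

test_that("models round-trip through JSON serialization", {
  pool <- easy_patch_pool(6)
  model <- fit_exg_detector(pool, seed = 3)
  f <- withr::local_tempfile(fileext = ".json")
  write_model(model, f)
  back <- read_model(f)
  expect_equal(back$weights, model$weights)
  expect_equal(back$tau, model$tau)
  expect_equal(back$offsets, model$offsets)
  p <- pool[[2]]
  expect_equal(predict_exg_detector(back, p$pixels),
               predict_exg_detector(model, p$pixels))
})
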