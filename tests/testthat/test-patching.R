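test_that("patch grids tile exactly, edge-shift, and overlap correctly", {
  g <- plan_grid(832, 832, 416, 0)
  expect_equal(g$xs, c(0, 416))
  expect_equal(nrow(g$origins), 4)

  g <- plan_grid(1000, 1000, 416, 0)
  expect_equal(g$xs, c(0, 416, 584)) # final origin flush with the edge
  expect_equal(nrow(g$origins), 9)

  g <- plan_grid(832, 832, 416, 0.5)
  expect_equal(g$xs, c(0, 208, 416))
  expect_equal(nrow(g$origins), 9)

  expect_error(plan_grid(100, 100, 416), "exceeds")
})

test_that("every pixel is covered by at least one patch", {
  for (dims in list(c(832, 832), c(1000, 700), c(501, 417))) {
    g <- plan_grid(dims[1], dims[2], 416, 0.5)
    expect_true(max(g$xs) + g$patch_size >= dims[1])
    expect_true(max(g$ys) + g$patch_size >= dims[2])
    expect_true(all(diff(g$xs) <= g$patch_size))
    expect_true(all(diff(g$ys) <= g$patch_size))
  }
})

test_that("annotations are clipped and kept by the area-fraction rule", {
  g <- plan_grid(832, 416, 416, 0)
  # box straddling the x = 416 boundary: 30% in the left patch, 70% right
  img <- toy_image(boxes(410, 100, 430, 120), 832, 416)
  ps <- extract_patches(img, g, keep_fraction = 0.5)
  left <- ps[[1]]; right <- ps[[2]]
  expect_equal(nrow(left$boxes), 0)
  expect_equal(nrow(right$boxes), 1)
  expect_equal(unlist(right$boxes[1, 1:4], use.names = FALSE),
               c(0, 100, 14, 120))

  # keep_fraction 0 retains the annotation in every overlapping patch
  ps0 <- extract_patches(img, g, keep_fraction = 0)
  expect_equal(nrow(ps0[[1]]$boxes), 1)
  expect_equal(nrow(ps0[[2]]$boxes), 1)

  # fully interior box appears once, unclipped
  img2 <- toy_image(boxes(100, 100, 130, 140), 832, 416)
  ps2 <- extract_patches(img2, g, keep_fraction = 0.5)
  expect_equal(unlist(ps2[[1]]$boxes[1, 1:4], use.names = FALSE),
               c(100, 100, 130, 140))
  expect_equal(nrow(ps2[[2]]$boxes), 0)
})

test_that("zero-overlap extraction with keep_fraction 0 conserves interior
           annotations", {
  withr::with_seed(21, {
    g <- plan_grid(192, 192, 96, 0)
    b <- random_int_boxes(20, lim = 20) # boxes within [0, 20]^2
    # shift each box wholly into the interior of one of the four cells
    off_x <- sample(c(5, 101), 20, replace = TRUE)
    off_y <- sample(c(5, 101), 20, replace = TRUE)
    b$min_x <- b$min_x + off_x; b$max_x <- b$max_x + off_x
    b$min_y <- b$min_y + off_y; b$max_y <- b$max_y + off_y
    img <- toy_image(b, 192, 192)
    ps <- extract_patches(img, g, keep_fraction = 0)
    expect_equal(sum(vapply(ps, function(p) nrow(p$boxes), integer(1))),
                 nrow(b))
  })
})

test_that("augmentation transforms boxes consistently with pixels", {
  px <- flat_patch(416)
  px <- paint_rect(px, 10, 20, 30, 40)
  p <- structure(list(image_id = "a", origin = c(x = 0, y = 0),
                      patch_size = 416, pixels = px,
                      boxes = boxes(10, 20, 30, 40)),
                 class = "patch_record")
  hf <- augment_patch(p, rotate = FALSE, hflip = TRUE, vflip = FALSE)
  expect_equal(unlist(hf$boxes[1, 1:4], use.names = FALSE),
               c(386, 20, 406, 40))
  # pixels moved with the box: the flipped rectangle is where the box says
  expect_true(all(hf$pixels[21:40, 387:406, 2] == 0.65))

  # involution: flipping twice restores everything
  hf2 <- augment_patch(hf, rotate = FALSE, hflip = TRUE, vflip = FALSE)
  expect_equal(hf2$boxes, p$boxes)
  expect_equal(hf2$pixels, p$pixels)

  idp <- augment_patch(p, rotate = FALSE, hflip = FALSE, vflip = FALSE)
  expect_equal(idp, p)

  # rotation: (x, y) -> (s - y, x), areas and counts preserved
  rp <- augment_patch(p, rotate = TRUE, hflip = FALSE, vflip = FALSE)
  expect_equal(unlist(rp$boxes[1, 1:4], use.names = FALSE),
               c(376, 10, 396, 30))
  expect_equal(box_area(rp$boxes), box_area(p$boxes))
  expect_true(all(rp$pixels[11:30, 377:396, 2] == 0.65))
})

test_that("random augmentation preserves annotation count and areas", {
  withr::with_seed(9, {
    b <- random_int_boxes(6, lim = 90)
    p <- structure(list(image_id = "a", origin = c(x = 0, y = 0),
                        patch_size = 96, pixels = NULL, boxes = b),
                   class = "patch_record")
    for (i in 1:20) {
      a <- augment_patch(p)
      expect_equal(nrow(a$boxes), nrow(b))
      expect_equal(sort(box_area(a$boxes)), sort(box_area(b)))
      expect_true(all(a$boxes$min_x >= 0 & a$boxes$max_x <= 96))
    }
  })
})

test_that("single-patch merging passes predictions through", {
  g <- plan_grid(416, 416, 416, 0)
  preds <- list(boxes(c(10, 100), c(10, 100), c(30, 130), c(30, 130),
                      confidence = c(0.9, 0.8)))
  out <- merge_patch_predictions(preds, g)
  expect_equal(nrow(out), 2)
})

test_that("ownership keeps exactly one copy of a duplicated detection", {
  # image 624x416, patches at x-origins 0 and 208; centers x = 208 and 416,
  # midline x = 312: an object at image x-center 300 belongs to patch 1
  g <- plan_grid(624, 416, 416, 0.5)
  expect_equal(g$xs, c(0, 208))
  obj_a <- boxes(290, 100, 310, 120, confidence = 0.9)    # center x = 300
  obj_b <- boxes(82, 100, 102, 120, confidence = 0.85)    # same box, local
  out <- merge_patch_predictions(list(obj_a, obj_b), g)
  expect_equal(nrow(out), 1)
  expect_equal(out$confidence, 0.9)
  expect_equal(out$min_x, 290)

  # ... and an object at x-center 330 belongs to patch 2
  obj_a2 <- boxes(320, 100, 340, 120, confidence = 0.9)
  obj_b2 <- boxes(112, 100, 132, 120, confidence = 0.85)
  out2 <- merge_patch_predictions(list(obj_a2, obj_b2), g)
  expect_equal(nrow(out2), 1)
  expect_equal(out2$confidence, 0.85)
  expect_equal(out2$min_x, 320)
})

test_that("near-duplicates surviving ownership are removed by merge NMS", {
  g <- plan_grid(624, 416, 416, 0.5)
  # centers straddle the x = 312 midline, so both survive ownership;
  # their IoU is 400/480 = 0.83 > 0.4, so NMS must drop the weaker one
  a <- boxes(300, 100, 322, 120, confidence = 0.9)  # center 311 -> patch 1
  b <- boxes(94, 100, 116, 120, confidence = 0.7)   # image (302,..,324,..)
  out <- merge_patch_predictions(list(a, b), g, nms_iou = 0.4)
  expect_equal(nrow(out), 1)
  expect_equal(out$confidence, 0.9)
})

test_that("predictions outside their source patch are rejected", {
  g <- plan_grid(624, 416, 416, 0.5)
  bad <- boxes(400, 100, 430, 120, confidence = 0.9) # exceeds patch width
  expect_error(merge_patch_predictions(list(bad, boxes()), g),
               "outside its source patch")
})

test_that("round trip: a perfect patch detector reconstructs ground truth", {
  withr::with_seed(31, {
    # objects smaller than half a patch, scattered over a 416x416 image
    b <- data.frame(min_x = c(30, 150, 290, 60, 340, 200),
                    min_y = c(40, 90, 30, 300, 330, 208),
                    max_x = c(60, 185, 330, 95, 376, 240),
                    max_y = c(75, 120, 65, 340, 370, 245),
                    confidence = NA_real_)
    img <- toy_image(b, 416, 416)
    g <- plan_grid(416, 416, 208, 0.5)
    ps <- extract_patches(img, g, keep_fraction = 0.5)
    preds <- lapply(ps, function(p) {
      x <- p$boxes; x$confidence <- 1.0; x
    })
    out <- merge_patch_predictions(preds, g, nms_iou = 0.4)
    m <- match_detections(out, b, eval_thresholds(0.9, 0.5))
    expect_equal(image_accuracy(m), 1.0)
  })
})
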