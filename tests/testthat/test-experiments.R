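# Most experiment mechanics are exercised with the mock detector (training-
# free) on tiny benchmarks; the reference detector's scientific behavior is
# covered in test-detector.R and test-acceptance.R.

make_pool <- function(n = 40, seed = 13) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      structure(list(image_id = paste0("im", (i - 1) %/% 4 + 1),
                     set_id = paste0("set", (i - 1) %/% 10 + 1),
                     origin = c(x = 0, y = 0), patch_size = 96,
                     pixels = NULL, boxes = random_int_boxes(3, lim = 90)),
                class = "patch_record")
    })
  })
}

test_that("training-set sampling is uniform, exact, and seeded", {
  pool <- make_pool(40)
  all40 <- sample_training_set(pool, 40, seed = 2)
  expect_setequal(vapply(all40, `[[`, character(1), "image_id"),
                  vapply(pool, `[[`, character(1), "image_id"))
  expect_length(sample_training_set(pool, 0, seed = 2), 0)
  s <- sample_training_set(pool, 10, seed = 3)
  keys <- vapply(s, function(p) paste(p$image_id, p$origin[1], p$origin[2],
                                      paste(p$boxes$min_x, collapse = ",")),
                 character(1))
  expect_false(anyDuplicated(keys) > 0)
  expect_identical(sample_training_set(pool, 10, seed = 3), s)
  expect_error(sample_training_set(pool, 41, seed = 1), "only 40")
})

test_that("replication summaries use the n-1 standard error", {
  s <- summarize_replicates(c(1, 2, 3))
  expect_equal(unname(s["mean"]), 2.0)
  expect_equal(unname(s["se"]), 1 / sqrt(3), tolerance = 1e-10)
  expect_equal(unname(summarize_replicates(5)["se"]), 0.0)
  expect_equal(unname(summarize_replicates(rep(2, 6))["se"]), 0.0)
  expect_error(summarize_replicates(numeric()), "no values")
})

test_that("relevance analysis: exhaustive case equals the full-suite
           difference", {
  dv <- c(a = 0.8, b = 0.7, c = 0.6)
  nd <- rbind(m1 = c(0.9, 0.5, 0.5), m2 = c(0.6, 0.65, 0.55))
  out <- relevance_analysis(dv, nd, n_range = 3)
  expect_true(out$exact)
  expect_equal(out$n_subsets, 1)
  expect_equal(out$mean_diff, mean(dv) - max(rowMeans(nd)))
})

test_that("relevance analysis reproduces the specialist-vs-generalist
           crossover", {
  # every set has its own specialist model (excellent there, poor
  # elsewhere); the diverse model is uniformly decent
  dv <- rep(0.70, 6)
  names(dv) <- paste0("s", 1:6)
  nd <- diag(0.95 - 0.40, 6) + 0.40
  rownames(nd) <- paste0("spec", 1:6)
  out <- relevance_analysis(dv, nd, n_range = c(1, 6))
  expect_true(all(out$exact))
  # n = 1: the best single-set model usually wins over the diverse model
  expect_lt(out$mean_diff[out$n == 1], 0)
  # n = K: the diverse model wins on the whole suite
  expect_gt(out$mean_diff[out$n == 6], 0)
})

test_that("resampled relevance estimates agree with exhaustive enumeration", {
  withr::with_seed(19, {
    K <- 10
    dv <- runif(K, 0.5, 0.8); names(dv) <- paste0("s", 1:K)
    nd <- matrix(runif(4 * K, 0.3, 0.8), 4, K)
  })
  # force the resampling path (choose(10, 5) = 252 > 120 subsets drawn)
  est <- relevance_analysis(dv, nd, n_range = 5, n_resamples = 120, seed = 4)
  expect_false(est$exact)
  subsets <- utils::combn(K, 5, simplify = FALSE)
  diffs <- vapply(subsets, function(ss) {
    mean(dv[ss]) - max(rowMeans(nd[, ss, drop = FALSE]))
  }, numeric(1))
  se <- stats::sd(diffs) / sqrt(120)
  expect_lt(abs(est$mean_diff - mean(diffs)), 3 * se)
  # per-subset best can differ from the global best
  glob <- relevance_analysis(dv, nd, n_range = 5, n_resamples = 120, seed = 4,
                             best = "global")
  expect_true(is.finite(glob$mean_diff))
})

test_that("mixed-to-test moves one image per set and preserves sizes", {
  bm <- tiny_benchmark(seed = 6, n_train_images = 2, n_id = 1, n_ood = 2)
  mixed <- mixed_to_test_split(bm, seed = 1)
  n_train <- function(b) sum(vapply(b$train_sets,
                                    function(s) length(s$images), integer(1)))
  expect_equal(n_train(mixed), n_train(bm))
  for (i in seq_along(mixed$ood_test_sets)) {
    expect_equal(length(mixed$ood_test_sets[[i]]$images),
                 length(bm$ood_test_sets[[i]]$images) - 1)
  }
  # moved ids are in the training pool and out of the OOD sets
  ood_ids <- function(b) unlist(lapply(b$ood_test_sets, function(s)
    vapply(s$images, `[[`, character(1), "id")))
  train_ids <- function(b) unlist(lapply(b$train_sets, function(s)
    vapply(s$images, `[[`, character(1), "id")))
  moved <- setdiff(ood_ids(bm), ood_ids(mixed))
  expect_length(moved, 2)
  expect_true(all(moved %in% train_ids(mixed)))
  expect_false(any(moved %in% ood_ids(mixed)))

  one_img <- tiny_benchmark(seed = 6, n_train_images = 2, n_id = 1, n_ood = 1)
  expect_error(mixed_to_test_split(one_img), "fewer than 2")
})

test_that("experiment drivers produce complete, labeled result tables", {
  bm <- tiny_benchmark(seed = 6, n_train_images = 3, n_id = 1, n_ood = 1)
  det <- mock_detector()
  pool <- build_patch_pool(bm)

  spec <- experiment_spec("size", sizes = c(4, length(pool)),
                          replications = 2, seed = 5)
  res <- run_size_series(spec, bm, det, pool = pool)
  acc <- res[res$metric == "accuracy", ]
  expect_equal(nrow(acc), 2 * 2 * 2) # sizes x reps x splits
  expect_setequal(unique(acc$split), c("id_test", "ood_test"))
  expect_true(all(acc$value >= 0 & acc$value <= 1))
  expect_error(run_size_series(experiment_spec("size", sizes = 10000),
                               bm, det, pool = pool), "exceeds the pool")

  dspec <- experiment_spec("diversity", replications = 2, seed = 5)
  dres <- run_diversity_experiment(dspec, bm, det, pool = pool)
  expect_setequal(unique(dres$split), "ood_test")
  conds <- unique(dres$condition)
  expect_true("diverse" %in% conds)
  expect_length(grep("^nondiverse:", conds), 2)
  tab <- diversity_accuracy_table(dres)
  expect_equal(dim(tab$nondiverse_acc), c(2, 2)) # 2 models x 2 OOD sets
  expect_error(run_diversity_experiment(
    experiment_spec("diversity", budget = 10000), bm, det, pool = pool),
    "exceeds the pool of training set")

  qspec <- experiment_spec("quality", dilation_levels = c(0, 4),
                           removal_levels = c(0, 0.5), replications = 1,
                           train_size = 8, seed = 5)
  qres <- run_quality_experiment(qspec, bm, det, pool = pool)
  expect_setequal(unique(qres$condition),
                  c("dilation:0", "dilation:4", "removal:0", "removal:0.5"))
  expect_true(all(qres$value[qres$metric == "count_error"] >= 0))
})

test_that("experiments re-run byte-identically from the same master seed", {
  bm <- tiny_benchmark(seed = 6, n_train_images = 3, n_id = 1, n_ood = 1)
  det <- reference_detector()
  pool <- build_patch_pool(bm)
  spec <- experiment_spec("size", sizes = c(8, 12), replications = 2,
                          seed = 31)
  r1 <- run_size_series(spec, bm, det, pool = pool)
  r2 <- run_size_series(spec, bm, det, pool = pool)
  expect_identical(r1, r2)
  # and a different master seed changes the draws
  r3 <- run_size_series(experiment_spec("size", sizes = c(8, 12),
                                        replications = 2, seed = 32),
                        bm, det, pool = pool)
  expect_false(identical(r1$value, r3$value))
})

test_that("one-set diversity degenerates to near-identical conditions", {
  bm <- tiny_benchmark(seed = 8, k_train = 1, k_ood = 1, n_train_images = 3,
                       n_id = 1, n_ood = 1)
  det <- reference_detector()
  spec <- experiment_spec("diversity", replications = 2, seed = 3)
  res <- run_diversity_experiment(spec, bm, det)
  acc <- res[res$metric == "accuracy", ]
  dv <- mean(acc$value[acc$condition == "diverse"])
  nd <- mean(acc$value[acc$condition != "diverse"])
  expect_lt(abs(dv - nd), 0.15)
})
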