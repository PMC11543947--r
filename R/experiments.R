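#' Experiment specification
#'
#' Desk-scale defaults: training-set sizes 100..3200 patches, 3 replications
#' per condition, a diversity budget equal to the smallest per-set patch
#' pool, dilation levels 0..8 px and the printed removal probabilities, and
#' 800-patch training sets for the quality study. The full-scale study
#' protocol (sizes up to 38,891 patches, budget 630, dilation 0..32 step 2,
#' 16,000-patch quality training sets, 5 replications) is expressible
#' through the same fields for use against the real dataset.
#'
#' @param kind one of `"size"`, `"diversity"`, `"quality"`,
#'   `"mixed_to_test"`.
#' @param sizes training-set sizes (patches) for the size study.
#' @param replications model replications per condition.
#' @param budget fixed patch budget for the diversity study; `NULL` means
#'   the smallest per-set pool size.
#' @param dilation_levels,removal_levels noise grids for the quality study.
#' @param train_size fixed training-set size for the quality study.
#' @param seed master seed; every cell derives its own stream from it.
#' @return an `experiment_spec` object.
#' @export
experiment_spec <- function(kind = c("size", "diversity", "quality",
                                     "mixed_to_test"),
                            sizes = c(100, 200, 400, 800, 1600, 3200),
                            replications = 3,
                            budget = NULL,
                            dilation_levels = c(0, 2, 4, 6, 8),
                            removal_levels = c(0, 0.1, 0.25, 0.5, 0.75, 0.9),
                            train_size = 800,
                            seed = 1) {
  kind <- match.arg(kind)
  stopifnot(all(sizes > 0), replications >= 1, train_size > 0,
            all(dilation_levels >= 0),
            all(removal_levels >= 0 & removal_levels <= 1))
  structure(list(kind = kind, sizes = sizes, replications = replications,
                 budget = budget, dilation_levels = dilation_levels,
                 removal_levels = removal_levels, train_size = train_size,
                 seed = seed),
            class = "experiment_spec")
}

#' Build the training patch pool of a benchmark
#'
#' Extracts non-overlapping patches with annotations from every training
#' image. Each patch record carries its source set id, so the pool supports
#' both pooled (diverse) and per-set (non-diverse) sampling.
#'
#' @param benchmark a `field_benchmark`.
#' @param keep_fraction clipped-annotation retention rule (default 0.5).
#' @return list of `patch_record`s.
#' @export
build_patch_pool <- function(benchmark, keep_fraction = 0.5) {
  ps <- benchmark$patch_size
  pool <- list()
  for (s in benchmark$train_sets) {
    grid <- plan_grid(s$width, s$height, ps, 0)
    for (im in s$images) {
      pool <- c(pool, extract_patches(im, grid, keep_fraction))
    }
  }
  pool
}

#' Sample a training set from the patch pool
#'
#' Uniform sampling without replacement, deterministic given `seed`.
#'
#' @param pool list of `patch_record`s.
#' @param n number of patches to draw (`n <= length(pool)`).
#' @param seed RNG seed.
#' @return a list of `n` patch records.
#' @export
sample_training_set <- function(pool, n, seed = 1) {
  if (n > length(pool)) {
    stop("requested ", n, " patches but the pool has only ", length(pool))
  }
  if (n == 0) return(list())
  idx <- withr::with_seed(seed, sample.int(length(pool), n))
  pool[idx]
}

result_row <- function(experiment, condition, replication, split, set_id,
                       metric, value) {
  data.frame(experiment = experiment, condition = condition,
             replication = replication, split = split,
             set_id = set_id, metric = metric, value = value,
             stringsAsFactors = FALSE)
}

eval_rows <- function(detector, model, benchmark, experiment, condition,
                      replication, splits = c("id_test", "ood_test"),
                      with_count_error = FALSE,
                      ood_sets = NULL) {
  rows <- list()
  for (split in splits) {
    sets <- if (split == "id_test") benchmark$id_test_sets
            else if (!is.null(ood_sets)) ood_sets
            else benchmark$ood_test_sets
    ev <- evaluate_sets(detector, model, sets, benchmark$patch_size)
    agg <- aggregate_accuracy(ev$accuracy, ev$set_id)
    rows[[length(rows) + 1]] <- result_row(
      experiment, condition, replication, split, NA_character_,
      "accuracy", agg$split)
    rows[[length(rows) + 1]] <- result_row(
      experiment, condition, replication, split, names(agg$per_set),
      "set_accuracy", unname(agg$per_set))
    if (with_count_error) {
      rows[[length(rows) + 1]] <- result_row(
        experiment, condition, replication, split, NA_character_,
        "count_error", count_error(ev$n_pred, ev$n_anno))
    }
  }
  do.call(rbind, rows)
}

#' Training-set size experiment
#'
#' For each size and replication, samples that many patches from the pooled
#' training sets without replacement, fits the detector, and evaluates split
#' accuracy on both the ID and OOD test sets via the tiled-inference
#' pipeline.
#'
#' @param spec an [experiment_spec()].
#' @param benchmark a `field_benchmark`.
#' @param detector a `detector_contract`.
#' @param pool optional prebuilt [build_patch_pool()] result.
#' @return a long-format results data.frame (experiment, condition,
#'   replication, split, set_id, metric, value).
#' @export
run_size_series <- function(spec, benchmark, detector, pool = NULL) {
  if (is.null(pool)) pool <- build_patch_pool(benchmark)
  if (max(spec$sizes) > length(pool)) {
    stop("largest size (", max(spec$sizes), ") exceeds the pool (",
         length(pool), " patches)")
  }
  rows <- list()
  for (size in spec$sizes) {
    for (rep in seq_len(spec$replications)) {
      train <- sample_training_set(
        pool, size, derive_seed(spec$seed, "size", size, rep, "sample"))
      model <- detector$fit(train, derive_seed(spec$seed, "size", size, rep,
                                               "fit"))
      rows[[length(rows) + 1]] <- eval_rows(
        detector, model, benchmark, "size", as.character(size), rep)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Training-set diversity experiment
#'
#' Every model gets the same patch budget. Non-diverse models draw their
#' budget from a single training set (one family of models per set); diverse
#' models draw from the pool of all training sets. All models are evaluated
#' on the OOD test sets only. The default budget is the size of the smallest
#' per-set pool, i.e. the largest budget every non-diverse condition can
#' meet.
#'
#' @inheritParams run_size_series
#' @return long-format results; non-diverse conditions are named
#'   `"nondiverse:<set id>"`, the pooled condition `"diverse"`.
#' @export
run_diversity_experiment <- function(spec, benchmark, detector, pool = NULL) {
  if (is.null(pool)) pool <- build_patch_pool(benchmark)
  set_ids <- vapply(pool, function(p) p$set_id, character(1))
  per_set <- split(seq_along(pool), set_ids)
  budget <- spec$budget
  if (is.null(budget)) budget <- min(lengths(per_set))
  too_small <- names(per_set)[lengths(per_set) < budget]
  if (length(too_small) > 0) {
    stop("budget (", budget, ") exceeds the pool of training set ",
         too_small[1], " (", length(per_set[[too_small[1]]]), " patches)")
  }
  rows <- list()
  for (sid in names(per_set)) {
    sub <- pool[per_set[[sid]]]
    for (rep in seq_len(spec$replications)) {
      train <- sample_training_set(
        sub, budget, derive_seed(spec$seed, "nondiv", sid, rep, "sample"))
      model <- detector$fit(train,
                            derive_seed(spec$seed, "nondiv", sid, rep, "fit"))
      rows[[length(rows) + 1]] <- eval_rows(
        detector, model, benchmark, "diversity",
        paste0("nondiverse:", sid), rep, splits = "ood_test")
    }
  }
  for (rep in seq_len(spec$replications)) {
    train <- sample_training_set(
      pool, budget, derive_seed(spec$seed, "diverse", rep, "sample"))
    model <- detector$fit(train, derive_seed(spec$seed, "diverse", rep, "fit"))
    rows[[length(rows) + 1]] <- eval_rows(
      detector, model, benchmark, "diversity", "diverse", rep,
      splits = "ood_test")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Diversity-versus-relevance resampling analysis
#'
#' For each number of evaluation sets `n`, draws subsets of `n` OOD test
#' sets and computes, per subset, the difference between the diverse model's
#' accuracy and the accuracy of the best-performing non-diverse model *on
#' that subset* (subset accuracy = mean of per-set accuracies). Reports the
#' mean difference per `n`. When the number of distinct subsets
#' `choose(K, n)` does not exceed `n_resamples`, all subsets are enumerated
#' exactly instead of sampled.
#'
#' @param diverse_acc named numeric vector: the diverse model's mean
#'   accuracy per OOD set (averaged over replications).
#' @param nondiverse_acc numeric matrix (non-diverse models x OOD sets) of
#'   mean per-set accuracies, with matching column order.
#' @param n_range values of `n` to evaluate (default `1:K`).
#' @param n_resamples number of random subsets per `n` (default 1000).
#' @param seed RNG seed for the subset draws.
#' @param best `"per_subset"` (the maximum is taken over models on each
#'   subset, the default) or `"global"` (the single model best on the full
#'   suite is used for every subset).
#' @return data.frame with columns `n`, `mean_diff`, `n_subsets`, `exact`.
#' @export
relevance_analysis <- function(diverse_acc, nondiverse_acc, n_range = NULL,
                               n_resamples = 1000, seed = 1,
                               best = c("per_subset", "global")) {
  best <- match.arg(best)
  K <- length(diverse_acc)
  stopifnot(ncol(nondiverse_acc) == K)
  if (is.null(n_range)) n_range <- seq_len(K)
  if (any(n_range < 1 | n_range > K)) {
    stop("n_range values must be between 1 and the number of OOD sets (",
         K, ")")
  }
  global_best <- which.max(rowMeans(nondiverse_acc))
  one_diff <- function(subset) {
    dv <- mean(diverse_acc[subset])
    nd <- if (best == "per_subset") {
      max(rowMeans(nondiverse_acc[, subset, drop = FALSE]))
    } else {
      mean(nondiverse_acc[global_best, subset])
    }
    dv - nd
  }
  rows <- lapply(n_range, function(n) {
    n_sub <- choose(K, n)
    if (n_sub <= n_resamples) {
      subsets <- utils::combn(K, n, simplify = FALSE)
      diffs <- vapply(subsets, one_diff, numeric(1))
      data.frame(n = n, mean_diff = mean(diffs), n_subsets = length(subsets),
                 exact = TRUE)
    } else {
      diffs <- withr::with_seed(derive_seed(seed, "relevance", n), {
        vapply(seq_len(n_resamples), function(i) {
          one_diff(sample.int(K, n))
        }, numeric(1))
      })
      data.frame(n = n, mean_diff = mean(diffs), n_subsets = n_resamples,
                 exact = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Extract the per-set accuracy table of a diversity experiment
#'
#' Averages replications per condition and returns the inputs
#' [relevance_analysis()] expects.
#'
#' @param results the [run_diversity_experiment()] output.
#' @return list with `diverse_acc` (named vector) and `nondiverse_acc`
#'   (models x sets matrix).
#' @export
diversity_accuracy_table <- function(results) {
  r <- results[results$metric == "set_accuracy" & results$split == "ood_test", ]
  agg <- stats::aggregate(value ~ condition + set_id, data = r, FUN = mean)
  sets <- sort(unique(agg$set_id))
  conds <- sort(unique(agg$condition))
  m <- matrix(NA_real_, length(conds), length(sets),
              dimnames = list(conds, sets))
  for (i in seq_len(nrow(agg))) {
    m[agg$condition[i], agg$set_id[i]] <- agg$value[i]
  }
  list(diverse_acc = m["diverse", ],
       nondiverse_acc = m[setdiff(conds, "diverse"), , drop = FALSE])
}

#' Mixed-to-test split
#'
#' Moves one randomly chosen image from each OOD test set into the training
#' split (replacing one randomly removed image of the corresponding training
#' set, so the total training image count is preserved) and excludes the
#' moved images from OOD evaluation. Requires equally many training and OOD
#' sets, each with at least 2 images.
#'
#' @param benchmark a `field_benchmark`.
#' @param seed RNG seed for the image choices.
#' @return a modified `field_benchmark`.
#' @export
mixed_to_test_split <- function(benchmark, seed = 1) {
  tr <- benchmark$train_sets; od <- benchmark$ood_test_sets
  if (length(tr) != length(od)) {
    stop("mixed-to-test requires equally many training and OOD sets")
  }
  for (s in c(tr, od)) {
    if (length(s$images) < 2) {
      stop("set ", s$id, " has fewer than 2 images")
    }
  }
  withr::with_seed(seed, {
    for (i in seq_along(od)) {
      move <- sample.int(length(od[[i]]$images), 1)
      drop <- sample.int(length(tr[[i]]$images), 1)
      moved_img <- od[[i]]$images[[move]]
      od[[i]]$images <- od[[i]]$images[-move]
      tr[[i]]$images <- c(tr[[i]]$images[-drop], list(moved_img))
    }
  })
  benchmark$train_sets <- tr
  benchmark$ood_test_sets <- od
  benchmark
}

#' Mixed-to-test experiment
#'
#' Trains `replications` models on the original full training pool and on
#' the mixed-to-test pool (same size, partly composed of former OOD images)
#' and evaluates both on the ID sets and the reduced OOD sets.
#'
#' @inheritParams run_size_series
#' @return long-format results with conditions `"original"` and
#'   `"mixed_to_test"`.
#' @export
run_mixed_experiment <- function(spec, benchmark, detector) {
  mixed <- mixed_to_test_split(benchmark,
                               derive_seed(spec$seed, "mixed_split"))
  rows <- list()
  for (cond in c("original", "mixed_to_test")) {
    bm <- if (cond == "original") benchmark else mixed
    pool <- build_patch_pool(bm)
    for (rep in seq_len(spec$replications)) {
      model <- detector$fit(pool, derive_seed(spec$seed, "mixed", cond, rep))
      # both conditions are scored on the reduced OOD sets for comparability
      rows[[length(rows) + 1]] <- eval_rows(
        detector, model, benchmark, "mixed_to_test", cond, rep,
        ood_sets = mixed$ood_test_sets)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Training-set quality (annotation noise) experiment
#'
#' For each noise type (dilation, removal), level, and replication: corrupt
#' the full patch pool, sample a fixed-size training set from the corrupted
#' pool (noise before subsampling), fit, and record OOD split accuracy and
#' count error.
#'
#' @inheritParams run_size_series
#' @return long-format results; conditions are `"dilation:<N>"` and
#'   `"removal:<P>"`.
#' @export
run_quality_experiment <- function(spec, benchmark, detector, pool = NULL) {
  if (is.null(pool)) pool <- build_patch_pool(benchmark)
  if (spec$train_size > length(pool)) {
    stop("train_size exceeds the patch pool")
  }
  rows <- list()
  run_cell <- function(cfg, cond, rep) {
    corrupted <- corrupt_dataset(pool, cfg)
    train <- sample_training_set(
      corrupted, spec$train_size,
      derive_seed(spec$seed, "quality", cond, rep, "sample"))
    model <- detector$fit(train,
                          derive_seed(spec$seed, "quality", cond, rep, "fit"))
    eval_rows(detector, model, benchmark, "quality", cond, rep,
              splits = "ood_test", with_count_error = TRUE)
  }
  for (N in spec$dilation_levels) {
    for (rep in seq_len(spec$replications)) {
      cond <- paste0("dilation:", N)
      cfg <- noise_config(dilation_max = N, removal_prob = 0,
                          seed = derive_seed(spec$seed, "noise", cond, rep))
      rows[[length(rows) + 1]] <- run_cell(cfg, cond, rep)
    }
  }
  for (P in spec$removal_levels) {
    for (rep in seq_len(spec$replications)) {
      cond <- paste0("removal:", P)
      cfg <- noise_config(dilation_max = 0, removal_prob = P,
                          seed = derive_seed(spec$seed, "noise", cond, rep))
      rows[[length(rows) + 1]] <- run_cell(cfg, cond, rep)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run an experiment by kind
#'
#' Dispatches on `spec$kind` to the matching experiment driver.
#'
#' @inheritParams run_size_series
#' @return a long-format results data.frame.
#' @export
run_experiment <- function(spec, benchmark, detector) {
  switch(spec$kind,
         size = run_size_series(spec, benchmark, detector),
         diversity = run_diversity_experiment(spec, benchmark, detector),
         quality = run_quality_experiment(spec, benchmark, detector),
         mixed_to_test = run_mixed_experiment(spec, benchmark, detector))
}

#' Mean and standard error across replications
#'
#' @param x numeric vector of per-replication values (at least one).
#' @return named numeric `c(mean, se)`; `se` is the sample standard
#'   deviation (n - 1 denominator) divided by `sqrt(n)`, and 0 for a single
#'   value.
#' @examples
#' summarize_replicates(c(1, 2, 3)) # mean 2, se 1/sqrt(3)
#' @export
summarize_replicates <- function(x) {
  if (length(x) == 0) stop("no values to summarize")
  se <- if (length(x) == 1) 0 else stats::sd(x) / sqrt(length(x))
  c(mean = mean(x), se = se)
}
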