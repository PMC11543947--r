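#' Write annotations in COCO-style JSON
#'
#' The documented subset: `images` (id, file_name, width, height),
#' `annotations` (id, image_id, bbox `[x, y, width, height]` with top-left
#' origin, area, category_id), and a single `categories` entry. Image and
#' annotation ids are assigned consecutively from 1 in input order, and
#' field order is fixed, so identical inputs produce byte-identical files.
#'
#' @param images list of `field_image`s (pixels not required; `width`,
#'   `height`, `id`, `boxes` are).
#' @param path output file.
#' @param category category name written to the file.
#' @return `path`, invisibly.
#' @export
write_coco <- function(images, path, category = "seedling") {
  img_entries <- list(); ann_entries <- list()
  ann_id <- 0L
  for (i in seq_along(images)) {
    im <- images[[i]]
    img_entries[[i]] <- list(id = i, file_name = paste0(im$id, ".png"),
                             width = im$width, height = im$height)
    b <- im$boxes
    if (nrow(b) > 0) {
      for (j in seq_len(nrow(b))) {
        ann_id <- ann_id + 1L
        ann_entries[[ann_id]] <- list(
          id = ann_id, image_id = i,
          bbox = c(b$min_x[j], b$min_y[j],
                   b$max_x[j] - b$min_x[j], b$max_y[j] - b$min_y[j]),
          area = (b$max_x[j] - b$min_x[j]) * (b$max_y[j] - b$min_y[j]),
          category_id = 1L)
      }
    }
  }
  doc <- list(images = img_entries, annotations = ann_entries,
              categories = list(list(id = 1L, name = category)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a COCO-style annotation file
#'
#' Validates the documented subset on load: every `bbox` must have strictly
#' positive width and height (errors name the offending annotation id), and
#' every annotation must reference a listed image. Boxes are converted to
#' `(min_x, min_y, max_x, max_y)`.
#'
#' @param path the JSON file.
#' @return list of `field_image`s with `pixels = NULL`; `file_name` is kept
#'   in each record's `meta`.
#' @export
read_coco <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("malformed JSON in ", path, ": ",
                                           conditionMessage(e)))
  for (f in c("images", "annotations")) {
    if (is.null(doc[[f]])) stop("missing '", f, "' field in ", path)
  }
  imgs <- list()
  id_map <- character()
  for (e in doc$images) {
    if (is.null(e$id) || is.null(e$width) || is.null(e$height)) {
      stop("image entry missing id/width/height in ", path)
    }
    key <- as.character(e$id)
    imgs[[key]] <- structure(
      list(id = sub("\\.png$", "", e$file_name %||% key),
           domain_id = NA_character_, set_id = NULL,
           width = e$width, height = e$height, pixels = NULL,
           boxes = boxes(), meta = list(file_name = e$file_name)),
      class = "field_image")
  }
  for (a in doc$annotations) {
    bb <- unlist(a$bbox)
    if (length(bb) != 4) {
      stop("annotation ", a$id %||% "?", " has a malformed bbox")
    }
    if (bb[3] <= 0 || bb[4] <= 0) {
      stop("annotation ", a$id %||% "?",
           " has non-positive bbox width or height")
    }
    key <- as.character(a$image_id)
    if (is.null(imgs[[key]])) {
      stop("annotation ", a$id %||% "?", " references unknown image ",
           a$image_id)
    }
    imgs[[key]]$boxes <- rbind(imgs[[key]]$boxes,
                               data.frame(min_x = bb[1], min_y = bb[2],
                                          max_x = bb[1] + bb[3],
                                          max_y = bb[2] + bb[4],
                                          confidence = NA_real_))
  }
  unname(imgs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an image set to disk (PNG tiles + COCO JSON + set metadata)
#'
#' @param set an `image_set`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_image_set <- function(set, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (im in set$images) {
    png::writePNG(im$pixels, file.path(dir, paste0(im$id, ".png")))
  }
  write_coco(set$images, file.path(dir, "annotations.json"))
  meta <- list(id = set$id, role = set$role, seed = set$seed,
               width = set$width, height = set$height,
               n_images = length(set$images),
               params = if (!is.null(set$params))
                 lapply(unclass(set$params), identity) else NULL)
  yaml::write_yaml(meta, file.path(dir, "set.yaml"))
  invisible(dir)
}

#' Read an image set written by [write_image_set()]
#'
#' @param dir the set directory.
#' @param load_pixels whether to load the PNG tiles (default `TRUE`).
#' @return an `image_set`.
#' @export
read_image_set <- function(dir, load_pixels = TRUE) {
  meta <- yaml::read_yaml(file.path(dir, "set.yaml"))
  images <- read_coco(file.path(dir, "annotations.json"))
  images <- lapply(images, function(im) {
    im$set_id <- meta$id
    im$domain_id <- meta$id
    if (load_pixels) {
      f <- file.path(dir, paste0(im$id, ".png"))
      if (!file.exists(f)) stop("missing image file: ", f)
      im$pixels <- png::readPNG(f)
    }
    im
  })
  structure(list(id = meta$id, role = meta$role, params = meta$params,
                 seed = meta$seed, width = meta$width, height = meta$height,
                 images = images),
            class = "image_set")
}

#' Write a benchmark to disk with a dataset manifest
#'
#' Writes every image set under `dir/sets/<id>/` and a `manifest.yaml`
#' listing each set's id, role, relative path, and seed.
#'
#' @param benchmark a `field_benchmark`.
#' @param dir output directory.
#' @return the manifest path, invisibly.
#' @export
write_benchmark <- function(benchmark, dir) {
  dir.create(file.path(dir, "sets"), recursive = TRUE, showWarnings = FALSE)
  entries <- list()
  all_sets <- c(benchmark$train_sets, benchmark$id_test_sets,
                benchmark$ood_test_sets)
  for (s in all_sets) {
    write_image_set(s, file.path(dir, "sets", s$id))
    entries[[length(entries) + 1]] <-
      list(id = s$id, role = s$role, path = file.path("sets", s$id),
           seed = s$seed)
  }
  manifest <- list(dataset = "synthetic-field-benchmark",
                   patch_size = benchmark$patch_size,
                   seed = benchmark$seed, sets = entries)
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' Load and validate a dataset manifest
#'
#' Checks that set ids are unique, roles are within the allowed enum, and
#' every referenced set directory (with its annotation file) exists;
#' relative paths are resolved against the manifest's own directory.
#'
#' @param path path to `manifest.yaml`.
#' @return a `dataset_manifest` list.
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- yaml::read_yaml(path)
  root <- dirname(normalizePath(path))
  roles <- c("train", "id_test", "ood_test")
  ids <- vapply(m$sets, function(s) as.character(s$id), character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate set id in manifest: ", ids[duplicated(ids)][1])
  }
  for (s in m$sets) {
    if (!(s$role %in% roles)) {
      stop("set ", s$id, " has unknown role '", s$role, "' (expected ",
           paste(roles, collapse = "/"), ")")
    }
    p <- file.path(root, s$path)
    if (!dir.exists(p)) stop("set directory missing: ", p)
    af <- file.path(p, "annotations.json")
    if (!file.exists(af)) stop("annotation file missing: ", af)
  }
  m$root <- root
  structure(m, class = "dataset_manifest")
}

#' Load a benchmark from a manifest
#'
#' @param manifest a [load_manifest()] result.
#' @param load_pixels whether to load PNG pixel data.
#' @return a `field_benchmark`.
#' @export
read_benchmark <- function(manifest, load_pixels = TRUE) {
  sets <- lapply(manifest$sets, function(s) {
    read_image_set(file.path(manifest$root, s$path), load_pixels)
  })
  roles <- vapply(sets, function(s) s$role, character(1))
  first <- sets[[1]]
  structure(list(train_sets = sets[roles == "train"],
                 id_test_sets = sets[roles == "id_test"],
                 ood_test_sets = sets[roles == "ood_test"],
                 width = first$width, height = first$height,
                 patch_size = manifest$patch_size, seed = manifest$seed),
            class = "field_benchmark")
}

#' Experimental adapter for the deposited canola seedling dataset
#'
#' Best-effort mapping of a manually downloaded and unpacked copy of the
#' public canola seedling dataset (DOI 10.5281/zenodo.11055599) into a
#' [load_manifest()]-style manifest. The deposit's internal layout is not
#' formally documented, so this adapter scans for set directories that
#' contain an annotation JSON and infers roles from directory names
#' containing "train", "id", or "ood". It never downloads anything and
#' never writes into the data directory. Experimental: expect to adjust the
#' role inference for your local copy.
#'
#' @param root_dir directory of the unpacked deposit.
#' @return a `dataset_manifest`.
#' @export
zenodo_adapter <- function(root_dir) {
  if (!dir.exists(root_dir)) {
    stop("dataset directory not found: ", root_dir,
         "\nDownload and unpack the deposit from ",
         "https://doi.org/10.5281/zenodo.11055599 first; this package ",
         "never fetches it automatically.")
  }
  anns <- list.files(root_dir, pattern = "\\.json$", recursive = TRUE,
                     full.names = TRUE)
  anns <- anns[basename(anns) %in%
                 c("annotations.json", "instances.json", "coco.json")]
  if (length(anns) == 0) {
    found <- list.files(root_dir, recursive = FALSE)
    stop("unrecognized dataset layout under ", root_dir,
         "; no per-set annotation JSONs found. Top-level entries: ",
         paste(utils::head(found, 20), collapse = ", "))
  }
  entries <- lapply(anns, function(a) {
    d <- dirname(a)
    nm <- tolower(basename(d))
    role <- if (grepl("ood", nm)) "ood_test"
            else if (grepl("id", nm)) "id_test"
            else "train"
    list(id = basename(d), role = role,
         path = sub(paste0("^", normalizePath(root_dir), "/?"), "",
                    normalizePath(d)))
  })
  structure(list(dataset = "zenodo-canola-seedlings", patch_size = 416,
                 seed = NA, sets = entries,
                 root = normalizePath(root_dir)),
            class = "dataset_manifest")
}

#' Write / read an experiment results table as CSV
#'
#' Plain deterministic CSV (no row names), losslessly round-tripping the
#' long-format results produced by the experiment drivers.
#'
#' @param results a results data.frame.
#' @param path CSV path.
#' @return `read_results` returns the data.frame.
#' @export
write_results <- function(results, path) {
  utils::write.csv(results, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(condition = "character",
                                 set_id = "character"))
}
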