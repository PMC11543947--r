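Package: seedlingbench
Title: Benchmarking Generalization of Aerial Seedling Detection Pipelines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the size, diversity, and annotation
    quality of a training set affect in-distribution and out-of-distribution
    performance of aerial plant-detection pipelines. Provides the detection
    accuracy metric used by the Global Wheat Head Detection challenge with
    hierarchical image/set/split aggregation, tiled (patch-based) inference
    with overlap-aware merging of bounding-box predictions, annotation noise
    models (box dilation and box removal), a multi-domain synthetic
    crop-field image generator with ground-truth seedling boxes, a
    CPU-trainable reference detector behind a pluggable detector contract,
    and orchestration for training-set size, diversity, and quality
    experiments with replication and resampling analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    utils,
    withr,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
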