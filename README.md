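# seedlingbench

Detection models that count crop seedlings in aerial imagery are usually
trained on a handful of acquisition sessions and then deployed on fields,
dates, and conditions they have never seen. `seedlingbench` is an R package
for studying that generalization gap at desk scale: it implements the
evaluation metric, the tiled-inference machinery, annotation-noise models, a
multi-domain synthetic field-image generator, a CPU-trainable reference
detector, and the experiment protocols needed to ask how the **size**,
**diversity**, and **annotation quality** of a training set shape
in-distribution (ID) versus out-of-distribution (OOD) detection performance.

It is aimed at researchers in agricultural image analysis who want a fully
reproducible, download-free environment for protocol development,
teaching, and method sanity-checking before committing GPU time to real
datasets.

## The metric and the experiments

Per image, detection accuracy follows the Global Wheat Head Detection
challenge:

    Accuracy = TP / (TP + FN + FP)

where a prediction participates only if its confidence exceeds 0.5
(strictly) and matches an annotation greedily at IoU >= 0.5. Image
accuracies average within an image set (one acquisition session = one
visual domain), and set accuracies average within a split. The counting
companion metric is the mean absolute difference between predicted and
annotated object counts per image.

Three experiment drivers reproduce the qualitative phenomena of interest:

* `run_size_series()` — learning curves over training-set sizes, ID vs OOD;
* `run_diversity_experiment()` + `relevance_analysis()` — single-domain
  (non-diverse) vs pooled (diverse) training at a fixed patch budget, and
  the diversity-versus-relevance resampling analysis;
* `run_quality_experiment()` — box-dilation versus box-removal annotation
  noise, tracking both box accuracy and count error.

## Worked example

```r
library(seedlingbench)

# A small benchmark: 3 training domains (+ matched ID test sets) and
# 3 fresh OOD domains, 20 training images per set.
bm <- build_benchmark(k_train = 3, k_ood = 3, n_train_images = 20,
                      n_id_images = 2, n_ood_images = 2, seed = 42)
pool <- build_patch_pool(bm)       # 240 annotated 96 px training patches
det <- reference_detector()

model <- det$fit(sample_training_set(pool, 200, seed = 1), seed = 1)
ev_id  <- evaluate_sets(det, model, bm$id_test_sets, bm$patch_size)
ev_ood <- evaluate_sets(det, model, bm$ood_test_sets, bm$patch_size)
round(c(id  = aggregate_accuracy(ev_id$accuracy,  ev_id$set_id)$split,
        ood = aggregate_accuracy(ev_ood$accuracy, ev_ood$set_id)$split), 3)
#>    id   ood
#> 0.566 0.435
```

Training on 200 patches from three domains gives 0.566 ID accuracy and
0.435 on unseen domains — the ID–OOD gap the full experiments quantify.
(The reference detector is a deliberately simple segmentation-plus-scoring
model; its absolute accuracies are not comparable to deep detectors, and
only qualitative orderings carry meaning.)

## Package layout

* `R/boxes.R` — box geometry, IoU, NMS, matching, the accuracy metric;
* `R/patching.R` — patch grids, annotation clipping, augmentation,
  overlap-aware merging of patch predictions;
* `R/noise.R` — dilation and removal annotation noise;
* `R/synthetic.R` — domain parameters and the field-image renderer;
* `R/detector.R` — the detector contract and the reference detector;
* `R/evaluate.R`, `R/experiments.R` — tiled inference and the experiment
  drivers;
* `R/io.R` — COCO-style JSON, PNG image sets, dataset manifests, results
  CSV, and an experimental adapter for the public canola seedling dataset
  (DOI 10.5281/zenodo.11055599; never downloaded automatically);
* `vignettes/seedlingbench-methods.Rmd` — the model, assumptions, and
  design choices in detail.
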