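---
title: "Methods: benchmarking generalization of aerial seedling detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: benchmarking generalization of aerial seedling detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Early-season plant population counts are a key indicator of field health for
canola producers. Detection models trained on aerial imagery can automate
those counts, but their accuracy degrades on *out-of-distribution* (OOD)
imagery — images from acquisition sessions (fields, dates, conditions) that
were not represented in training. `seedlingbench` provides a desk-scale,
fully synthetic environment for studying how three properties of a training
set — its **size**, its **diversity** (number of source domains), and its
**annotation quality** — shape the gap between in-distribution (ID) and OOD
detection performance.

Every component of the evaluation pipeline is first-class, tested code: the
metric, the tiled-inference machinery, the annotation-noise models, the data
generator, a trainable reference detector, and the experiment drivers.

## The accuracy metric

The primary metric is the per-image detection accuracy used by the Global
Wheat Head Detection challenge,

$$\mathrm{Accuracy} = \frac{TP}{TP + FN + FP},$$

where a true positive is an annotated box matched with a predicted box. A
prediction participates only if its confidence strictly exceeds 0.5, and a
match requires IoU of at least 0.5 (`eval_thresholds()`). Matching is
greedy: predictions are processed in descending confidence (ties broken by
input index) and each takes the still-unmatched annotation with the highest
IoU. The source metric definition says only that boxes "can be matched";
the deterministic greedy policy is this package's choice, matching common
detection-challenge practice, and the test suite pins *this* policy against
an independently coded brute-force oracle. An image with no annotations and
no confident predictions scores 1.0 — the detector made no mistake; this
resolves the 0/0 case of the formula.

Aggregation is hierarchical and unweighted: image accuracies are averaged
within an image set, and set accuracies are averaged within a split. A
five-image set counts as much as a fifty-image set, which matches how
multi-session field datasets are reported.

The companion counting metric, `count_error()`, is the mean absolute
difference between the number of confident predictions and the number of
annotations per image. It sees only cardinalities, never geometry — the
property that makes it diverge from box accuracy under loose-box noise.

## Tiled inference

Images are processed as fixed square patches (416 px at full scale; 96 px in
the desk benchmark). Training uses non-overlapping patches; inference uses
50% overlap. `plan_grid()` shifts the final patch flush with the image edge
rather than padding, so no synthetic pixels are introduced.

Merging patch predictions back to image level is the subtle step. A literal
"discard boxes whose centers fall in overlapping areas" rule can delete an
object from *every* patch when its center lies in a mutual-overlap zone. We
instead partition the image into ownership cells by nearest patch center
(Euclidean distance, ties to the lower row-major patch index): a prediction
survives iff its center lies in its source patch's cell. Every image point
is owned by exactly one patch, so dedup loses no object; greedy NMS at IoU
0.4 then removes residual near-duplicates straddling cell boundaries. With a
perfect per-patch detector this pipeline reconstructs ground truth exactly
for objects smaller than half a patch (verified in the acceptance suite).

Annotations clipped by a patch boundary are kept iff at least half their
area remains (`keep_fraction = 0.5`); augmentation applies a single 90°
clockwise rotation, a horizontal flip, and a vertical flip, each
independently with probability 0.5, which generates the dihedral symmetries
of the square.

## Annotation-noise models

Two noise families emulate real labeling defects:

* **Dilation (loose boxes).** Each box side is pushed outward by an
  independent draw from the discrete uniform on $\{0, \dots, N\}$ (order:
  min_x, min_y, max_x, max_y), then clipped to the frame. Mean expansion per
  side is $N/2$.
* **Removal (missing boxes).** Each box is deleted independently with
  probability $P$.

Noise is applied to the full patch pool *before* training-set subsampling,
matching the study protocol, and is driven entirely by the `noise_config()`
seed. The desk grids are $N \in \{0, 2, 4, 6, 8\}$ px and
$P \in \{0, 0.1, 0.25, 0.5, 0.75, 0.9\}$: desk objects are ~14 px across, so
desk $N$ spans the same dilation-to-object-size ratios as the full-scale
grid (0–32 px for ~50 px objects).

## The synthetic benchmark

`build_benchmark()` emulates the structure of a multi-session aerial
dataset: each image set is one *domain* governed by a `domain_params` vector
(plant density and row geometry, cotyledon size, foliage and soil color,
illumination, blur, sensor noise, weed and stubble pressure). Training and
ID-test sets share domain parameters ("same acquisition session"); OOD sets
draw fresh parameters from deliberately wider ranges on every shift axis —
object size, sharpness, occlusion, distractors, lighting, noise — so the OOD
split is systematically, but not impossibly, harder.

Seedlings are rendered as two opposed cotyledon ellipses around a center
disc with 0–4 leaf ellipses; the ellipse axes are calibrated so that the
orientation-averaged tight box of a leafless pair has mean side equal to
twice the `cotyledon_len` parameter (the nominal tip-to-tip span), giving a
checkable parameter-recovery property. Weeds come in two kinds, both *in
the crop's color family* so only shape separates crop from distractor:
scruffy multi-lobe blobs, and "mimics" — two-lobed weeds imitating a
cotyledon pair with the wrong proportions (unequal lobes, bent axis,
off-center joint). Each domain has its own weed flora: the `weed_species`
and `weed_mimicry` parameters set the local mimics' typical proportions,
bend, and prevalence, exactly as the species mix of real fields varies
between acquisition sessions. Mimics are the benchmark's hard negatives —
rejecting them requires a finely resolved decision boundary, which is what
makes training-set size *and* domain coverage matter to any downstream
classifier; without a per-domain hard-negative axis, a fixed-budget
single-domain training set would be as transferable as a pooled one, only
denser, and the diversity phenomenon would invert. Stubble is rendered as
pale straight straws, roughly half of which are drawn above the canopy and
occlude it. A seedling is annotated iff at least 30% of its pixels remain
visible under occluding stubble (the source data's annotation guidelines
leave occluded plants to annotator judgment; 30% is this package's fixed
rule). Annotations are the tight boxes of rendered pixels. Rendering order:
soil, under-stubble, plants and weeds, over-stubble, illumination scale,
Gaussian blur, sensor noise; everything is bit-reproducible from the seed.

Desk-scale defaults: 8 training + 8 OOD domains, 192×192 px images, 96 px
patches, 100 training images per set (a 3,200-patch pool), 3 ID-test and 6
OOD-test images per set. These sizes keep the full experiment sweeps within
minutes on one CPU; the full-scale layout (27+27 sets, 416 px patches) is
reachable through the same parameters. Two deliberate calibrations, made
while designing the generator: seedling lobes are at least ~2.6 px wide so
the detector's 3×3 morphological opening cannot erase a legal plant, and the
OOD blur range tops out at σ = 1.3 because beyond that (at this object
scale) vegetation segmentation produces *zero* proposals — an impossible
domain rather than a harder one, which is not what multi-session field
datasets look like.

What the generator does **not** emulate: perspective and orthomosaic
geometry, species diversity, within-image illumination gradients, sensor
PSF differences, or realistic plant morphology. Passing benchmarks here
demonstrates that the *pipeline and protocols* behave correctly and that
the qualitative orderings (size helps; diversity helps generalization;
noise types dissociate) are reproducible — not that any specific real-world
accuracy level would be attained.

## The reference detector

The study that motivates this package trained a GPU-scale single-stage
network; that is out of scope here by design. The pluggable detector
contract (`fit(patches, seed)` / `predict(model, pixels)`) is filled by a
deliberately simple, fast, CPU-trainable reference detector chosen to be
(a) *trainable*, so data-size and diversity effects manifest; (b)
*label-driven*, so annotation noise propagates; (c) *deterministic* given a
seed:

1. **Segmentation.** Excess-green index $2g - r - b$ on chromatic
   coordinates (illumination-invariant), thresholded at τ; 3×3 binary
   opening (background-padded; verified against a brute-force morphology
   oracle); 4-connected components; tight boxes filtered to an area window.
2. **Threshold search.** τ is picked from quantiles (probabilities
   0.85–0.935, bracketing the soil/vegetation boundary at typical canopy
   coverage) of the pooled index distribution by maximizing proposal-stage
   F1 on a seeded patch subsample whose size *scales with the pool* (one in
   eight patches, 12–400). Small training sets estimate noisier thresholds —
   the first mechanism by which training-set size matters.
3. **Scoring.** Candidates are labeled positive iff IoU ≥ 0.5 with a
   training annotation. Each candidate gets 7 shape/spectral features (log
   area, aspect, fill, index mean/sd, ring contrast, elongation — the
   index-based ones expressed relative to the patch's own vegetation scale,
   so they transfer across blur and lighting domains) plus an
   *appearance-memory* feature: the Epanechnikov-kernel-weighted fraction
   of positives among all stored training candidates near the candidate's
   36-dimensional normalized crop embedding (leave-one-out during
   fitting). The exemplar memory grows with the training set, and the
   compact-support kernel means its purity estimates genuinely sharpen as
   the memory fills — the second and dominant size mechanism, playing the
   role that parameter-rich appearance learning plays in a deep detector.
   A logistic model over the z-scored features is fit by 200 full-batch
   gradient-descent steps (learning rate 0.4, ridge 1e-4, seeded init) on
   a capped query subsample; confidence is the sigmoid score.
4. **Size offsets.** The mean signed margin between matched proposals and
   their annotations is added to predictions. This is what lets dilation
   noise *visibly* inflate predicted boxes (degrading localization while
   leaving counts nearly intact) instead of being absorbed.

If training annotations exist but no proposal matches any of them, fitting
returns an explicit always-reject model rather than failing — necessary for
the high-removal-noise cells of the quality experiment.

## Experiment protocols

All three studies run against the same benchmark and detector contract, log
long-format result tables, and derive every random stream from the master
seed via `derive_seed()` (a Lehmer mixing chain), so any cell can be
re-executed in isolation and full reruns are byte-identical.

* **Size.** Sizes {100, 200, 400, 800, 1600, 3200} patches sampled without
  replacement from the pooled training sets, 3 replications, evaluated on
  ID and OOD splits. (Full-scale preset: 250–38,891 and 5 replications.)
* **Diversity.** Fixed budget = the smallest per-set pool (the largest
  budget every non-diverse condition can meet; 400 patches in the default
  benchmark, the analogue of the full-scale 630). Non-diverse models draw
  from one set; diverse models from the pool; OOD evaluation only. The
  resampling analysis (`relevance_analysis()`) draws subsets of n OOD sets
  and compares the diverse model against the best non-diverse model *on
  each subset* ("best" resolved per subset by default; the global-best
  variant is an option). Subsets are enumerated exhaustively whenever
  `choose(K, n)` does not exceed the resample budget.
* **Quality.** For each noise type and level: corrupt the pool, sample a
  fixed-size training set (800 patches), fit, and record OOD accuracy and
  count error.
* **Mixed-to-test.** One image moves from each OOD set into training while
  one training image per set is dropped (which training image an OOD image
  "replaces" is unspecified at the source; we remove one uniformly chosen
  image per training set, preserving per-set balance and total size). Both
  the original and mixed models are evaluated on the reduced OOD sets.

The reference detector has no epoch trajectory, so there is no
lowest-training-loss checkpoint selection; the final fit is the model. This
is a documented divergence from deep-learning practice.

## Numerical conventions

Boxes are continuous, 0-based, origin top-left; pixel (r, c) covers the
half-open cell [c−1, c) × [r−1, r). IoU uses geometric areas (the
rasterization oracle agrees exactly for integer boxes). Confidence ties in
NMS and matching break by ascending input index; IoU ties in matching break
by ascending annotation index; ownership ties break to the lower row-major
patch index. The confidence filter is strict (> 0.5) per the challenge
convention, the IoU filter inclusive (≥ 0.5). Dilation with N = 0 consumes
no random draws. Degenerate (zero-area) boxes are rejected at every
boundary (constructors, COCO load, matching).

## Known limitations

* The reference detector's absolute accuracies (~0.8 on an easy sparse
  domain, ~0.6 ID / ~0.5 OOD on the default benchmark) are not comparable
  to deep-detector results; only qualitative orderings are claimed, and
  only those are asserted.
* Ownership-cell merging assumes axis-aligned square grids.
* The generator's domains are low-dimensional; real acquisition-session
  variation is far richer, so diversity effects here are a lower bound on
  the real phenomenon's complexity.
* The dataset adapter for the public deposit is best-effort and marked
  experimental; the deposit's internal layout is not formally documented.
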