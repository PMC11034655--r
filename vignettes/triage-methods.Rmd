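---
title: "Methods: patch-based triage of cervical biopsy whole-slide images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: patch-based triage of cervical biopsy whole-slide images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the pipeline

Cervical biopsies are reported into four diagnostic categories with a
natural severity order: normal/inflammation < low grade (HPV change,
CIN 1) < high grade (CIN 2/3) < malignant (squamous carcinoma,
adenocarcinoma, CGIN and other malignant tumours). Digitized slides are
gigapixel multi-resolution pyramids: level 0 is the full-resolution scan
(0.25 µm/pixel by convention) and each higher level halves both
dimensions, so one pixel at level m covers a 2^m x 2^m level-0 block
(1024 pixels at level 5). A slide cannot be loaded whole, so the
pipeline works patch-wise and aggregates:

1. **Grid patch finding.** A thumbnail is read at `mag_level`; square
   level-0 patches of side `patch_size` appear there as cells of
   `patch_size / 2^mag_level` thumbnail pixels. The grid starts at the
   top-left corner, is non-overlapping, and drops partial edge cells.
   Thumbnail cell origins times `2^mag_level` give level-0 origins.
2. **Tissue detection.** A thumbnail pixel is tissue if it is darker
   than `luminance_max` (default 0.88) of full white or more saturated
   than `saturation_min` (default 0.07). A patch is tissue if *any* of
   its pixels is tissue — deliberately conservative so slivers of
   tissue are never discarded.
3. **Max-severity labelling.** Each tissue patch takes the most severe
   category over all annotation polygons that touch it: one malignant
   pixel makes the patch malignant. Polygon overlap is evaluated at
   thumbnail resolution by default (the granularity at which the grid
   is defined); an exact level-0 mode exists and is pinned to a
   brute-force point-in-polygon oracle in the test-suite.
4. **Sampling.** Balanced mode draws equal counts per category and
   trains with cross-entropy. Imbalanced mode — the configuration tuned
   for malignant sensitivity — keeps *all* malignant patches,
   downsamples normal patches to the malignant count, keeps all low-
   and high-grade patches, and trains with focal loss.
5. **Patch classification.** A pluggable classifier maps an RGB patch
   to four category probabilities (details below).
6. **Heatmaps.** Per category, a grid with one cell per patch holding
   that patch's probability; non-tissue cells are zero and excluded
   from the tissue area. On tissue cells the four grids sum to one.
7. **Slide features.** Two schemes summarize the heatmaps (below).
8. **Slide classification.** Gradient-boosted trees (or a random forest
   with randomized hyperparameter search), with model selection that
   prefers malignant sensitivity.

## Patch classifier: protocol and default model

Training follows a fixed protocol: SGD with momentum 0.9, learning rate
0.001, weight decay 0.0005, the rate halved every 2 epochs, at most 20
epochs, early stopping after 10 epochs without validation-accuracy
improvement, and the best-validation checkpoint returned. Augmentation
is a random rotation from {0°, 90°, 180°, 270°} plus colour jitter with
half-ranges brightness 0.25, contrast 0.75, saturation 0.25, hue 0.04,
followed by per-channel normalization with mean 0.5 and sd 0.5 (inputs
in [0, 1] map to [-1, 1]).

The focal loss is −α_t (1 − p_t)^γ log p_t averaged over the batch,
with γ = 2 and α the normalized inverse class frequency by default
(γ = 0, α = 1 recovers cross-entropy exactly; the identity is pinned to
1e−10 in tests). Probabilities are clamped at 1e−12 before the log.

The *model* behind this protocol is a pluggable contract (`featurize` /
`forward` / `backward` over a parameter list), so any backbone can be
substituted. The desk-scale default is a one-hidden-layer perceptron
(48 tanh units) over 16 x 16 x 3 mean-pooled pixels concatenated with a
per-patch channel-centred copy of the same pooled pixels (each channel
minus its own within-patch mean). The centred copy is invariant to
additive per-channel stain shifts, which measurably improves
generalization to staining labs never seen in training, and keeps the
scale of the raw copy (variance scaling was rejected: on near-uniform
patches it amplifies noise). The raw copy retains absolute colour.
Minibatches of 8 keep the update count high within the 20-epoch
budget.

Because focal-loss training under boundary-label noise yields correct
but under-confident probabilities — while the heatmap feature schemes
threshold probabilities at absolute levels 0.5–0.9 — the trained model
carries a softmax temperature fitted on the validation set (temperature
scaling, `p^(1/T)` renormalized). Calibration cannot change the argmax,
so accuracy, early stopping and checkpoint selection are unaffected;
it only puts the probability scale where the thresholds expect it.

A seed-ensemble wrapper (`train_patch_ensemble`) trains several
members under the same protocol and averages their raw probabilities
before one ensemble-level calibration. It is deliberately *not* the
pipeline default: across synthetic cohorts, averaging reliably
suppresses scattered false-positive heatmap areas (raising overall
accuracy) but equally suppresses the weak true-malignant regions of
hard multilabel slides, lowering malignant sensitivity — the objective
this pipeline is tuned for. The default configuration (single model,
booster learning rate 0.1) was chosen by comparing candidate designs
on a bank of synthetic validation cohorts generated with seeds
disjoint from those used in the packaged end-to-end checks.

## Slide feature schemes

Let tissue area be the number of tissue cells. For a probability grid
and threshold t, `area_ratio` is the number of cells ≥ t over the
tissue area and `prob_area` is the summed probability of those cells
over the tissue area; both are non-increasing in t.

* **forest-90**: `area_ratio` and `prob_area` at thresholds 0.5–0.9
  (step 0.1) for the malignant, high-grade and low-grade heatmaps (30
  global features), plus 10 regional statistics (area, eccentricity,
  extent, bbox area, major axis length, max/mean/min intensity, bbox
  aspect ratio, solidity) for the 2 largest connected regions of each
  of those three heatmaps thresholded at 0.5 (60 regional features):
  90 values.
* **boosted**: `area_ratio` at 0.5/0.7/0.9 for malignant and high
  grade (6 global features), plus masked regional statistics for the 7
  largest malignant, 5 high-grade, 3 low-grade and 2 normal regions.
  The per-category masks keep 12 statistics for malignant, 11 for high
  grade (min intensity dropped), 9 for low grade (area, equivalent
  diameter and perimeter dropped) and 5 for normal (bbox area, major
  and minor axis length, mean intensity, filled area), giving
  6 + 84 + 55 + 27 + 10 = 182 values.

Missing regions are zero-padded so vectors have fixed length and fixed,
named column order. Connected components use 8-connectivity (the
standard blob-analysis default; pinned to a flood-fill oracle on 200
random masks). Regional statistics follow the usual regionprops
conventions: the second-moment ellipse of the pixel-center point set
(axis length 4·sqrt(eigenvalue); eccentricity 0 for a single cell),
extent = area / bbox area, solidity = area over the geometric area of
the convex hull of the pixel squares, filled area counts 4-connected
interior holes as filled, Euler number = 1 − number of holes,
equivalent diameter = diameter of the circle of equal area, and
perimeter = the count of unit edges between region and non-region
cells. Region intensity is the same category's probability grid.

## Slide classifiers

The boosted classifier uses 60 rounds of depth-3 trees with per-sample
weights 1.0 for malignant slides and 0.1 for every other category, so
the weighted loss is dominated by malignant errors. The fit runs 20
seeded restarts (row subsample 0.8, column subsample 0.8 make restarts
genuinely different) and keeps the restart with the highest malignant
sensitivity on the validation split, ties broken by accuracy.
`min_child_weight` defaults to 0: with 0.1-weighted samples on a
desk-scale cohort, the conventional default of 1 exceeds the summed
hessian of whole classes and silently vetoes every split, collapsing
the model to the largest-weight class.

The forest path samples 300 settings from a fixed grid (trees
100–1500 step 10; min samples to split {2, 5, 10}; min leaf size
{1, 2, 4}; max features {auto, sqrt, log2}; depth 10–110 step 10;
criterion {gini, entropy}; bootstrap {true, false}), scores each by
stratified 3-fold cross-validated accuracy, and refits the winner on
all training data. The ranger backend supports Gini impurity only, so
a sampled criterion of "entropy" is recorded but split on Gini; "auto"
and "sqrt" both map to sqrt(p) features per split.

## Inter-observer agreement

Nominal (unweighted) Cohen's kappa: κ = (p_o − p_e)/(1 − p_e) with
p_o the diagonal share of the agreement table and p_e from the marginal
products. For more than two observers the package reports the
arithmetic mean of all pairwise kappas. A packaged 200-sample
inter-observer study (three consultant pathologists re-annotating a
balanced subset, 50 slides per category) provides worked examples; the
observer-A-vs-original category table gives p_o = 0.955, p_e = 0.25,
κ = 0.94 exactly.

## The synthetic cohort generator

Real cohorts of annotated WSIs cannot ship with a package, so a
deterministic generator emulates the statistical structure the pipeline
relies on:

* near-white background (all channels ≥ 0.92) with faint scanner noise;
* tissue as a union of disc blobs painted with the normal texture;
* lesions as star-shaped polygons painted with category textures and
  recorded verbatim as annotations, so labels are exact by construction
  (an `annotation_jitter` option rescales polygons to emulate imprecise
  manual annotation);
* per-category textures differing in base colour and simulated nuclear
  density (dark spots), with green-channel means spaced > 0.1 so a
  depth-2 decision tree separates pure 64-pixel patches at ≥ 95%
  accuracy — guaranteeing that end-to-end tests measure the pipeline,
  not the texture model;
* a small deterministic per-lab RGB offset (±0.015) emulating the
  eight thickness-by-stain lab protocols, applied to tissue only;
* when lesion polygons overlap, painting runs in ascending severity so
  the most severe category owns the contested pixels, exactly matching
  the max-severity labelling rule.

Slides are written as PNG pyramids with level dims
`ceiling(dims0 / 2^L)` by 2x mean-pooling (odd dims edge-replicated),
and the same spec and seed produce byte-identical files.

What the generator does *not* emulate: nuclear morphology and texture
beyond spot density, fragmented biopsies, annotation ambiguity between
neighbouring grades, pen marks, blur, or scanner artefacts. Passing
end-to-end tests therefore demonstrates that the machinery — tiling,
labelling, training, aggregation, classification — recovers planted
structure; it does not certify clinical performance.

Default study conditions for the end-to-end checks: 120 slides over 4
labs with a uniform category mix, slide sides drawn from multiples of
64 in [512, 1024], 64-pixel patches indexed at mag level 3, imbalanced
sampling with focal loss, forest-90 features into the boosted
classifier, at seeds 0–2. Lesion radii are drawn as 0.18–0.30 of the
slide side: scaled to this desk-size geometry, a lesion then spans
several-to-many patches, as clinical lesions span large patch
neighbourhoods at full scale; much smaller radii would make nearly
every lesion patch a boundary patch, which tests label noise rather
than the pipeline. Under these conditions the test split is dominated
by two fully held-out labs, mirroring the study's lab-held-out design.

## Data splitting

All slides from `n_heldout_labs` randomly chosen labs plus a stratified
10% of every remaining lab form the test set; the rest split
train:valid = 2:1, stratified by category, subcategory and lab. Strata
under 3 slides fall back to category-level stratification with a
message. An optional relabel table overrides manifest labels before
splitting, mirroring post-annotation label corrections.

## Numerical choices and degenerate inputs

* Coordinates are 0-based, x = column, y = row, half-open rectangles;
  all annotation coordinates are level 0.
* Heatmap thresholding is inclusive (cell ≥ t), matching the ≥ 0.5
  rendering convention; prediction maps break probability ties towards
  the more severe category.
* Connected-component ordering: pixel count descending, ties by the
  row-major position of the topmost-leftmost cell.
* Bounding-box aspect ratio is width/height; the box always has
  positive height.
* Empty masks give empty region lists; slides with no tissue give
  empty inference results; zero tissue area is an error for global
  features.
* Every stochastic stage takes an explicit seed, and the pipeline
  derives per-stage seeds from one master seed.

## Known limitations

The hardest synthetic cases mirror the hardest clinical ones:
multilabel malignant slides whose high-grade lesion is larger than
their malignant lesion, read on a staining lab never seen in training.
There the malignant heatmap evidence is attenuated and the slide can
be called high grade — the same malignant-to-high-grade confusion the
clinical study reports. With roughly ten malignant slides in a
synthetic test split, a single such miss moves malignant sensitivity
by about nine points, so per-cohort sensitivity is quantized and
occasionally dips below 0.9 even though it averages about 0.95 across
cohorts.

* The default patch model is a compact MLP: sufficient for the
  generator's textures and for exercising every pipeline contract, but
  no substitute for a deep backbone on real histology. The factory
  contract is the intended extension point.
* Temperature calibration assumes the validation patches are
  representative; under severe validation shift the fitted temperature
  can be off.
* The forest search's criterion axis degenerates to Gini (backend
  limit), and "auto" equals "sqrt".
* Inference reads whole level-0 planes per slide through a per-slide
  cache; truly gigapixel slides would need windowed reads, which the
  `read_region` contract supports but the pipeline driver does not yet
  exploit.
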