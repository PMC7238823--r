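---
title: "Slice-wise convolutional ensembles: model, protocol and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Slice-wise convolutional ensembles: model, protocol and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cnnel)
```

## The method

`cnnel` implements a slice-wise ensemble approach to binary diagnosis from
MNI-space, skull-stripped, intensity-comparable T1-weighted volumes
(121 x 145 x 121 voxels at 1.5 mm), of the kind used to separate Alzheimer's
disease (AD) from healthy cognition (HC), or converting from non-converting
mild cognitive impairment (MCIc vs MCInc). The idea has three stages:

1. **Base classifiers.** The volume is re-sliced into three families of 2D
   slices (sagittal, coronal, transverse). Every other slice inside a
   per-axis crop window is kept — 40 + 50 + 33 = 123 positions at full scale
   — and one small convolutional network is trained per position on that
   slice across all training subjects. Slices are padded to a square
   (145 x 145 at full scale) with edge replication near the content and
   zero fill beyond.
2. **Two-stage majority-vote ensemble.** Each trained classifier is scored
   by accuracy on a held-out validation cohort never used for training or
   testing. Per axis, the N = 5 best generalizers are kept; an axis votes by
   the majority of its N members, and the final label is the majority of the
   three axis votes. N odd makes every vote tie-free (the suite checks all
   2^15 member configurations at N = 5). A flat 15-member vote is available
   via `ensemble_config(voting = "flat")`; the hierarchical scheme is the
   default because the two can disagree (one axis unanimous, two axes split
   3-2) and the two-stage description matches the published narrative.
3. **Localization.** The N selected coordinates per axis define N^3
   intersection points in MNI space (125 at N = 5). Each point is mapped
   through the inverse atlas affine, rounded to the nearest voxel (halfway
   ties toward negative infinity), and the label counts, accumulated over
   all repeats of cross-validation, rank regions by discriminative
   contribution. Points in unlabeled tissue are counted separately, so
   labeled + unlabeled always equals N^3 x repeats (10 x 125 = 1250 at the
   reference protocol, with the labeled sum strictly below that whenever
   points fall outside the atlas).

## The network

Each base classifier is an 8-layer network: six convolutions (kernels
3,3,3,1,1,1; strides 3,3,3,1,1,1; channels 1-32-64-128-256-512-1024) with a
3 x 3 max-pool after conv2..conv6 (strides 1,1,1,1,3), then fully connected
layers to 100 units and 2 softmax outputs. All convolutions and poolings use
"same" padding with `out = ceil(in / stride)`: this is the only padding
policy under which the flattened input of FC1 equals 4096 = 1024 x 2 x 2 for
a 145 x 145 input, so we document it as a derived constraint rather than a
free choice. Activations are leaky rectifiers; the negative slope is 0.01
(the conventional value; only the activation family is prescribed). The
final fully connected stage also uses the leaky rectifier before the softmax
layer. Weights use He fan-in initialization, natural for rectifier families.

Training minimizes cross-entropy with Adam (beta1 0.9, beta2 0.999 — the
optimizer's canonical values). `train_config()` defaults to the reference
regime: 30 epochs, learning rate 1e-4, batch size 200 (batches are capped at
the dataset size for small runs). A classifier is flagged `converged` when
it classifies **all original (non-augmented) training slices** correctly;
training always runs the full epoch budget and records the flag, since the
stopping behaviour on convergence is not specified.

Forward and backward passes are implemented in the package (im2col/col2im
and max-pool kernels in C++, matrix products through BLAS); gradients are
validated against central finite differences in the test suite.

### Desk-scale step sizes

Scaled-down runs in the tests and the acceptance script use 3-8 epochs at
learning rate 3e-4 on cohorts of 16-24 subjects. The full regime takes
thousands of optimizer steps (~80 batches/epoch x 30 epochs); a desk run
takes tens, so the step size is raised to keep the optimization budget
comparable. These are run-level choices passed through `train_config()`; the
defaults are unchanged.

## Cross-validation protocol

`make_stratified_folds()` builds repeated stratified k-fold plans (reference
protocol: k = 5, 10 repeats). Per-class allocation uses largest-remainder
rounding with remainders assigned to the folds with the smallest running
totals, processing classes from largest to smallest; for a 137 + 162 cohort
at k = 5 this reproduces the 239-train / 60-test split. Leakage guards are
structural: the validation cohort must be disjoint from the experiment
cohort (checked by subject id), augmented images carry a provenance flag and
are rejected by `select_top()` and `vote()`, and augmentation is applied
inside each training partition only.

Classifier selection happens **once per repeat**: slices are ranked by mean
validation accuracy across the repeat's folds, and each fold's ensemble
re-uses that repeat's selected coordinates with the fold's own trained
networks. (This matches the accounting in which 10 repeats yield
10 x 125 = 1250 intersection points; per-fold selection would yield five
times as many.) Ties in validation accuracy are broken toward the smaller
absolute MNI coordinate — central slices carry more tissue — then by
coordinate value; the rule is deterministic and documented. Per-repeat
metrics (accuracy, rank-based AUC with mid-rank ties, Matthews correlation)
are computed on the pooled held-out predictions of the repeat's folds, and
`aggregate_metrics()` reports mean and n-1 standard deviation across
repeats. `compare_accuracy_distributions()` reproduces the published
comparison recipe: an F test of variance homogeneity at 0.05 decides between
the pooled-variance t-test and the unequal-variance (Welch-corrected)
t-test, two-sided, with no multiple-testing correction.

## Class-balancing augmentation

Six label-preserving operations (rotation, translation, gamma correction,
additive Gaussian noise, scaling, random affine) expand each per-slice
training set. The per-class multipliers equalize augmented class totals:
`m_minority = round(n_majority * m_majority / n_minority)`, so 76 vs 134
originals at 10 new images per majority case yield 18 per minority case, and
totals 76(1 + 18x6) = 8284 and 134(1 + 10x6) = 8174 (16,458 images). Only
the operation *names* are prescribed; the magnitudes are this package's
choices, picked as mild perturbations standard for brain MRI and all
configurable in `augment_plan()`:

| operation   | default range                  | unit |
|-------------|--------------------------------|------|
| rotation    | +/- 10                         | degrees |
| translation | +/- 6                          | mm (converted by voxel size) |
| gamma       | exponent in [0.7, 1.4]         | — |
| noise       | sd 0.02                        | normalized intensity |
| scaling     | factor in [0.92, 1.08]         | — |
| affine      | 2 x 2 jitter +/- 6%            | — |

Geometric operations resample bilinearly with edge padding and preserve the
image size; outputs are clipped to [0, 1]. Every generated image draws from
an RNG substream keyed by (plan seed, slice, subject, operation, replicate),
so augmentation is reproducible under any execution order.

## The synthetic cohort generator

Real cohorts of preprocessed MRI are access-restricted, so the package ships
a generator that emulates exactly the properties the pipeline consumes:

- a fixed "anatomical" template (soft-edged ellipsoid with an interior
  gradient) giving slices non-trivial structure;
- subject noise: Gaussian fields (sd `noise_sd`, default 0.05 of the unit
  template scale) smoothed to `smooth_fwhm` (default 6 mm, a typical
  VBM-style smoothing width), one RNG substream per subject;
- a synthetic atlas: a brain-like mask tiled into Voronoi cells of random
  seed voxels — connected, convex-ish blobs standing in for a labeled
  parcellation, with a label -> name table and one or two behavioral-domain
  tags per region;
- a planted class effect: class-1 volumes shift mean intensity inside chosen
  regions by `effect_size * noise_sd` (a stand-in for regional atrophy;
  effect_size 5 in the recovery tests, 0 for null cohorts).

The default test grid is 24 x 28 x 24 — the full grid's aspect ratio at
desk scale; the slice-plan crop windows and the square side scale
proportionally, so small volumes traverse the identical code path
(full-scale generation works by passing the full shape). What the generator
deliberately does **not** model: anatomy, lesion morphology, scanner
artifacts, site effects, or intensity non-stationarity. Passing tests
therefore demonstrate that the machinery is correct and that the pipeline
recovers planted, compact, mean-shift signal — not that the classifier
performs at any particular level on clinical data.

## Numerical and design notes

- **Coordinates.** Voxel indices are 0-based; MNI coordinates are mm in
  RAS+ with the full-grid origin at (-90, -126, -72). The affine is
  authoritative; published coordinate lists rounded to integers are treated
  as display of half-millimeter grid values (the crop windows are fixed by
  their endpoints: voxel indices 19-97, 23-121, 29-93).
- **Slice extraction** requires the requested coordinate to land within
  0.25 voxel of a grid plane and reports the nearest valid coordinate
  otherwise.
- **Padding** splits any odd deficit with the extra cell on the high-index
  side; the edge-replication band is 4 voxels (configurable), zeros beyond.
- **Point-to-voxel rounding** is nearest-integer with halfway ties toward
  negative infinity; points outside the grid count as unlabeled.
- **Degenerate inputs** error early and descriptively: all-zero volumes
  (normalization), single-class training data, validation/training subject
  overlap, missing member slices at prediction time.
- **Problem sizes.** The suite's end-to-end runs use the 24 x 28 x 24 grid:
  chance-level calibration on an effect-free cohort of 12 + 12 subjects
  (k = 2, one repeat), and planted-region recovery over ten seeded runs of
  8 + 8 subjects with 6 + 6 validation, each accumulating three repeats of
  2-fold cross-validation before ranking regions (region ranking is defined
  over accumulated repeats). The acceptance script's from-scratch pipeline
  run uses 10 repeats at N = 5 with 2 folds — the intersection-point
  accounting depends only on repeats and N.

## Known limitations

- The 3D localization step assumes the discriminative structure is compact
  around the selected slices' crossings; a strongly non-convex or elongated
  region can place genuine slice crossings outside itself.
- With tiny validation cohorts, validation accuracy is coarse (granularity
  1/n), so slice ranking carries tie-break noise; accumulating repeats
  before ranking (as the reference protocol does) is what stabilizes the
  region table.
- Training is deterministic given seeds on a fixed BLAS; bitwise
  reproducibility across different BLAS builds is not guaranteed.
- The generator's planted effect is a mean shift; effects expressed purely
  in texture or shape are outside its vocabulary.
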