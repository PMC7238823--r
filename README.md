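# cnnel

Slice-wise convolutional ensembles for early detection of Alzheimer's
disease from structural MRI, with data-driven localization of the
discriminable brain regions.

## The problem

Clinically useful MRI markers of early Alzheimer's disease (AD) — and of
imminent conversion from mild cognitive impairment (MCI) to AD — are usually
read off a handful of slices chosen by prior anatomical knowledge. `cnnel`
implements the opposite, data-driven strategy for binary diagnosis from
preprocessed T1-weighted volumes (MNI space, skull-stripped, 121 x 145 x 121
voxels at 1.5 mm):

1. **One small CNN per slice position.** Volumes are re-sliced along the
   three anatomical axes; every other slice inside per-axis crop windows is
   kept (40 sagittal + 50 coronal + 33 transverse = 123 positions at full
   scale) and an 8-layer convolutional network (six convolutions, channels
   1→32→64→128→256→512→1024, leaky-ReLU, "same" padding, two fully
   connected layers, softmax) is trained per position. Class imbalance is
   handled by balanced slice augmentation: six operations (rotation,
   translation, gamma, noise, scaling, random affine) with per-class
   multipliers `m_minority = round(n_majority * m_majority / n_minority)`.
2. **Two-stage majority voting.** On a disjoint validation cohort each
   classifier's accuracy is measured; the top N = 5 per axis are kept. An
   axis votes by the majority of its 5 members and the final label is the
   majority of the three axis votes — tie-free by construction, verified
   exhaustively over all 2^15 member configurations.
3. **Region localization.** The 5 + 5 + 5 selected slice coordinates define
   5^3 = 125 intersection points in MNI space per cross-validation repeat.
   Accumulated over the 10 x 5-fold protocol (1250 points) and mapped
   through a labeled atlas, the per-region point counts rank brain regions
   by their contribution to the classification; behavioral-domain tags
   turn the table into a domain histogram.

Everything runs offline: a synthetic-cohort generator plants a mean-shift
class effect inside chosen regions of a synthetic atlas over smoothed noise,
so the whole pipeline — including recovery of the planted region — is
testable without access-restricted clinical data.

## Worked example

Desk-scale end-to-end run on synthetic data (24 x 28 x 24 grid — the full
grid's aspect ratio — same code path as full scale):

```r
library(cnnel)

atlas  <- make_atlas(c(24, 28, 24), n_regions = 6, seed = 1)
effect <- effect_spec(region_labels = 2, effect_size = 5, noise_sd = 0.05)
cohort <- simulate_cohort(atlas, effect, n_per_class = c(8, 8), seed = 101)
valid  <- simulate_cohort(atlas, effect, n_per_class = c(6, 6), seed = 201)
valid$info$subject_id <- paste0("val_", valid$info$subject_id)
for (i in seq_along(valid$volumes))
  valid$volumes[[i]]$subject_id <- valid$info$subject_id[i]

res <- run_experiment(
  cohort, valid, atlas,
  config   = train_config(epochs = 6, learning_rate = 3e-4, batch_size = 64),
  ensemble = ensemble_config(n_top = 3),
  repeats  = 3, k = 2, seed = 1)

res
glance(res)
res$regions
```

```
<cnnel_experiment> 3 repeat(s) x 2 folds, 9 ensemble members each
  accuracy 1.000 +/- 0.000
  auc      1.000 +/- 0.000
  mcc      1.000 +/- 0.000
  81 intersection points, 77 in labeled regions; top region: region_02
<cnnel_regions> 81 points, 77 in 4 labeled regions, 4 unlabeled
# A tibble: 4 x 3
  label name      n_points
  <int> <chr>        <int>
1     2 region_02       49
2     6 region_06       20
3     5 region_05        6
4     1 region_01        2
```

Reading the output: every held-out subject was classified correctly
(accuracy/AUC/MCC of 1 — the planted effect is deliberately strong at 5
noise-sd), and of the 3 x 27 intersection points defined by the selected
slices, the majority fall in `region_02` — exactly the region the effect was
planted in. On real data the same table ranks anatomical regions (e.g.
hippocampus, amygdala) by their discriminative contribution.

Useful pieces on their own: `slice_plan()` / `extract_slice()` /
`pad_to_square()` (slicing), `balance_multipliers()` /
`build_augmented_dataset()` (augmentation), `train_classifier()` /
`predict_proba()` (base CNNs), `select_top()` / `vote()` /
`compute_metrics()` / `compare_accuracy_distributions()` (ensembling),
`intersection_points()` / `count_regions()` / `domain_histogram()`
(localization), `autoplot()` on experiments, classifiers and region tables,
and a thin CLI (`exec/cnnel`) with `simulate`, `run-cv` and `localize`
subcommands.

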