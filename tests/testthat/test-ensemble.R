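test_that("compute_metrics matches hand-evaluated confusion-matrix formulas", {
  # confusion (TP, TN, FP, FN) = (40, 45, 5, 10)
  truth <- c(rep(1, 50), rep(0, 50))
  pred <- c(rep(1, 40), rep(0, 10), rep(1, 5), rep(0, 45))
  m <- compute_metrics(truth, pred)
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$mcc, (40 * 45 - 5 * 10) / sqrt(45 * 50 * 55 * 50),
               tolerance = 1e-12)
  expect_equal(round(m$mcc, 4), round(1750 / sqrt(45 * 50 * 55 * 50), 4))
  # perfect and inverted predictions
  expect_equal(compute_metrics(truth, truth, score = truth)$accuracy, 1)
  expect_equal(compute_metrics(truth, truth, score = truth)$mcc, 1)
  expect_equal(compute_metrics(truth, truth, score = truth)$auc, 1)
  expect_equal(compute_metrics(truth, 1 - truth)$mcc, -1)
  # single-class truth: undefined, not zero
  s <- compute_metrics(rep(1, 5), c(1, 1, 0, 1, 1), score = runif(5))
  expect_true(is.na(s$auc) && is.na(s$mcc))
})

test_that("rank-based AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::local_seed(8)
  for (i in 1:5) {
    truth <- rbinom(40, 1, 0.5)
    if (length(unique(truth)) < 2) next
    score <- runif(40) + 0.5 * truth
    score[sample(40, 5)] <- 0.5           # force ties
    ours <- compute_metrics(truth, as.integer(score > 0.7), score)$auc
    ref <- as.numeric(pROC::auc(pROC::roc(truth, score, quiet = TRUE,
                                          direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("accuracy comparison picks the variance treatment by the F test", {
  a <- c(0.80, 0.82, 0.84, 0.79, 0.81)
  b <- c(0.70, 0.90, 0.60, 0.95, 0.55)    # much larger variance
  p <- compare_accuracy_distributions(a, b)
  expect_true(attr(p, "welch"))
  expect_equal(as.numeric(p), t.test(a, b)$p.value, tolerance = 1e-12)
  b2 <- c(0.78, 0.80, 0.83, 0.82, 0.77)   # comparable variance
  p2 <- compare_accuracy_distributions(a, b2)
  expect_false(attr(p2, "welch"))
  expect_equal(as.numeric(p2), t.test(a, b2, var.equal = TRUE)$p.value,
               tolerance = 1e-12)
  # identical samples; permutation invariance; separated samples
  expect_equal(as.numeric(compare_accuracy_distributions(a, a)), 1)
  expect_equal(as.numeric(compare_accuracy_distributions(rep(0.5, 4), rep(0.5, 4))), 1)
  jit <- c(1e-4, -1e-4, 2e-4, -2e-4)
  p3 <- compare_accuracy_distributions(0.1 + jit, 0.9 + jit)
  expect_lt(as.numeric(p3), 0.001)
  p4 <- compare_accuracy_distributions(a, rev(b))
  expect_equal(as.numeric(p4), as.numeric(p), tolerance = 1e-12)
})

test_that("majority voting follows the hierarchical then flat definitions", {
  ax <- rep(c("sagittal", "coronal", "transverse"), each = 5)
  # axis votes (1, 1, 0) -> 1
  labs <- c(rep(1, 5), rep(1, 5), rep(0, 5))
  expect_equal(majority_vote(labs, ax), 1L)
  # 3-of-5 within an axis
  expect_equal(majority_vote(c(1, 1, 1, 0, 0), rep("coronal", 5)), 1L)
  # unanimity agrees under both schemes
  expect_equal(majority_vote(rep(1, 15), ax, "hierarchical"), 1L)
  expect_equal(majority_vote(rep(1, 15), ax, "flat"), 1L)
  expect_equal(majority_vote(rep(0, 15), ax, "hierarchical"), 0L)
  expect_equal(majority_vote(rep(0, 15), ax, "flat"), 0L)
})

test_that("hierarchical and flat voting disagree on the pinned configuration", {
  ax <- rep(c("sagittal", "coronal", "transverse"), each = 5)
  # one axis unanimous for 0, two axes split 3-2 for 1: 6 of 15 members say 1
  labs <- c(rep(0, 5), c(1, 1, 1, 0, 0), c(1, 1, 1, 0, 0))
  expect_equal(majority_vote(labs, ax, "hierarchical"), 1L)
  expect_equal(majority_vote(labs, ax, "flat"), 0L)
})

test_that("the 3 x 5 hierarchical vote never ties over all 2^15 configurations", {
  ax <- rep(c("sagittal", "coronal", "transverse"), each = 5)
  grid <- as.matrix(expand.grid(rep(list(0:1), 15)))
  votes <- apply(grid, 1, majority_vote, axis = ax, voting = "hierarchical")
  expect_equal(length(votes), 32768)
  expect_true(all(votes %in% c(0L, 1L)))
  # brute-force oracle: per-axis sums, then axis-label sum
  s <- grid[, 1:5] %*% rep(1, 5)
  c_ <- grid[, 6:10] %*% rep(1, 5)
  t_ <- grid[, 11:15] %*% rep(1, 5)
  oracle <- as.integer((as.integer(s >= 3) + as.integer(c_ >= 3) +
                          as.integer(t_ >= 3)) >= 2)
  expect_identical(unname(votes), oracle)
})

test_that("selection ranks by validation accuracy with the central-slice tie rule", {
  tbl <- tibble::tibble(
    axis = factor(rep("sagittal", 4), levels = cnnel:::axis_levels()),
    mm = c(28, -20, 4, -42),
    val_accuracy = c(0.8, 0.8, 0.6, 0.9))
  ranked <- cnnel:::rank_classifiers(tbl, 3)
  expect_equal(ranked$mm, c(-42, -20, 28))     # 0.9 first; tie -> |mm| smaller
  expect_equal(ranked$rank, 1:3)
})

test_that("select_top scores on validation data, guards leakage, builds the ensemble", {
  co <- tiny_cohort(c(6, 6), seed = 31)
  va <- tiny_cohort(c(5, 5), seed = 32, prefix = "val_")
  plan <- slice_plan(c(24, 28, 24))
  slices <- build_slice_dataset(co, plan)
  val_slices <- build_slice_dataset(va, plan)
  groups <- dplyr::group_split(dplyr::group_by(slices, axis, mm))
  # train only 3 positions per axis to keep this quick
  keep <- unlist(lapply(split(seq_along(groups),
                              vapply(groups, function(g) as.character(g$axis[1]), "")),
                        head, 3))
  clfs <- lapply(groups[sort(keep)], train_classifier, config = desk_config(epochs = 2))
  ens <- select_top(clfs, val_slices, ensemble_config(n_top = 3))
  expect_s3_class(ens, "cnnel_ensemble")
  expect_equal(nrow(ens$members), 9)
  expect_true(all(table(ens$members$axis) == 3))
  expect_true(all(diff(ens$members$rank[ens$members$axis == "sagittal"]) == 1))
  within_axis <- split(ens$members$val_accuracy, ens$members$axis)
  expect_true(all(vapply(within_axis, function(v) all(diff(v) <= 0), TRUE)))
  # leakage: validation containing a training subject aborts
  expect_error(select_top(clfs, slices, ensemble_config(n_top = 3)), "leakage")
  # fewer than n_top per axis
  expect_error(select_top(clfs, val_slices, ensemble_config(n_top = 5)),
               "available")
  # voting returns one row per subject with probability scores
  v <- vote(ens, val_slices)
  expect_equal(nrow(v), 10)
  expect_true(all(v$pred %in% 0:1))
  expect_true(all(v$score >= 0 & v$score <= 1))
  # missing member slice errors with the (axis, coordinate)
  sub <- val_slices[!(as.character(val_slices$axis) == ens$members$axis[1] &
                        abs(val_slices$mm - ens$members$mm[1]) < 1e-9), ]
  expect_error(vote(ens, sub), "missing slice")
})
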