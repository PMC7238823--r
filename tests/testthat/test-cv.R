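test_that("stratified folds reproduce the 239/60 split of a 137 + 162 cohort", {
  labels <- rep(c(0, 1), c(137, 162))
  folds <- make_stratified_folds(labels, k = 5, repeats = 1, seed = 1)
  sizes <- table(folds$fold)
  expect_equal(sum(sizes), 299)
  expect_identical(sort(unname(as.integer(sizes)), decreasing = TRUE),
                   c(60L, 60L, 60L, 60L, 59L))
  # most folds test on 60 (train on 239)
  expect_equal(sum(sizes == 60), 4)
  # per-fold class proportions within one subject of the cohort's
  for (f in 1:5) {
    in_f <- folds$index[folds$fold == f]
    n1 <- sum(labels[in_f] == 1)
    expect_lte(abs(n1 - length(in_f) * 162 / 299), 1)
  }
})

test_that("fold plans partition each repeat and are deterministic", {
  labels <- rep(c(0, 1), c(9, 13))
  folds <- make_stratified_folds(labels, k = 3, repeats = 4, seed = 9)
  for (r in 1:4) {
    sub <- folds[folds$repeat_id == r, ]
    expect_setequal(sub$index, seq_along(labels))
    expect_equal(nrow(sub), length(labels))
  }
  # repeats differ, same seed reproduces
  f1 <- folds$fold[folds$repeat_id == 1]
  f2 <- folds$fold[folds$repeat_id == 2]
  expect_false(identical(f1, f2))
  again <- make_stratified_folds(labels, k = 3, repeats = 4, seed = 9)
  expect_identical(folds, again)
  # tiny balanced case: every test fold is 1 + 1
  f55 <- make_stratified_folds(rep(c(0, 1), each = 5), k = 5, repeats = 1,
                               seed = 2)
  expect_true(all(table(f55$fold) == 2))
  expect_error(make_stratified_folds(c(0, 0, 1), k = 2, repeats = 1, seed = 1),
               "fewer than k")
})

test_that("aggregate_metrics computes sample mean and n-1 standard deviation", {
  m <- tibble::tibble(accuracy = c(0.8, 0.9), auc = c(0.85, 0.95),
                      mcc = c(0.6, 0.8))
  s <- aggregate_metrics(m)
  expect_equal(s$mean[s$metric == "accuracy"], 0.85)
  expect_equal(s$sd[s$metric == "accuracy"], sd(c(0.8, 0.9)))
  expect_equal(round(s$sd[s$metric == "accuracy"], 4), 0.0707)
  # single repeat: sd 0 with caveat; constant values: sd 0
  one <- aggregate_metrics(m[1, ])
  expect_true(all(one$sd == 0))
  expect_true(isTRUE(attr(one, "single_repeat")))
  const <- aggregate_metrics(tibble::tibble(accuracy = rep(0.7, 3),
                                            auc = rep(0.7, 3),
                                            mcc = rep(0.2, 3)))
  expect_true(all(const$sd == 0))
})

test_that("run_experiment returns the full accounting for repeats x folds", {
  a <- tiny_atlas()
  co <- tiny_cohort(c(5, 5), seed = 41)
  va <- tiny_cohort(c(4, 4), seed = 42, prefix = "val_")
  # narrow mm windows keep this to ~3 positions per axis
  plan <- slice_plan(c(24, 28, 24),
                     crop = list(sagittal = c(-6, 6), coronal = c(-8, 8),
                                 transverse = c(-5, 7)))
  res <- run_experiment(co, va, a, plan = plan,
                        config = desk_config(epochs = 2),
                        ensemble = ensemble_config(n_top = 3),
                        repeats = 2, k = 5, seed = 3)
  expect_s3_class(res, "cnnel_experiment")
  expect_equal(nrow(res$metrics), 2)
  expect_equal(res$metrics$repeat_id, 1:2)
  # N^3 x repeats intersection points, conserved in the region table
  expect_equal(nrow(res$points), 2 * 27)
  expect_equal(attr(res$regions, "total_points"), 54)
  expect_equal(sum(res$regions$n_points) + attr(res$regions, "unlabeled_count"),
               54)
  # selections: n_top per axis per repeat, drawn from the plan's coordinates
  expect_equal(nrow(res$selected), 2 * 9)
  expect_true(all(res$selected$mm %in% plan$coords$mm))
  # every subject predicted exactly once per repeat
  expect_equal(nrow(res$predictions), 2 * 10)
  expect_true(all(table(res$predictions$subject_id) == 2))
  # summary equals the aggregate of the per-repeat metrics
  expect_identical(res$summary$mean[res$summary$metric == "accuracy"],
                   mean(res$metrics$accuracy))
  # tidy/glance/autoplot interfaces
  expect_equal(nrow(tidy(res)), 2)
  g <- glance(res)
  expect_equal(g$repeats, 2)
  expect_equal(g$n_members, 9)
  expect_s3_class(autoplot(res), "ggplot")
  expect_s3_class(autoplot(res$regions), "ggplot")
})

test_that("experiments are reproducible and refuse leaking cohorts", {
  a <- tiny_atlas()
  co <- tiny_cohort(c(4, 4), seed = 51)
  va <- tiny_cohort(c(3, 3), seed = 52, prefix = "val_")
  plan <- slice_plan(c(24, 28, 24),
                     crop = list(sagittal = c(-3, 3), coronal = c(-4, 4),
                                 transverse = c(-3, 3)))
  r1 <- run_experiment(co, va, a, plan = plan, config = desk_config(epochs = 1),
                       ensemble = ensemble_config(n_top = 1), repeats = 1,
                       k = 2, seed = 4)
  r2 <- run_experiment(co, va, a, plan = plan, config = desk_config(epochs = 1),
                       ensemble = ensemble_config(n_top = 1), repeats = 1,
                       k = 2, seed = 4)
  expect_identical(r1$metrics, r2$metrics)
  expect_identical(r1$selected, r2$selected)
  expect_identical(r1$regions, r2$regions)
  expect_error(run_experiment(co, co, a, plan = plan), "leakage")
})

test_that("parallel training reproduces the serial experiment exactly", {
  skip_on_os("windows")
  a <- tiny_atlas()
  co <- tiny_cohort(c(4, 4), seed = 61)
  va <- tiny_cohort(c(3, 3), seed = 62, prefix = "val_")
  plan <- slice_plan(c(24, 28, 24),
                     crop = list(sagittal = c(-3, 3), coronal = c(-4, 4),
                                 transverse = c(-3, 3)))
  serial <- run_experiment(co, va, a, plan = plan,
                           config = desk_config(epochs = 1),
                           ensemble = ensemble_config(n_top = 1),
                           repeats = 1, k = 2, seed = 5, workers = 1)
  par <- run_experiment(co, va, a, plan = plan,
                        config = desk_config(epochs = 1),
                        ensemble = ensemble_config(n_top = 1),
                        repeats = 1, k = 2, seed = 5, workers = 2)
  expect_identical(serial$metrics, par$metrics)
  expect_identical(serial$selected, par$selected)
})
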