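# Repeated stratified cross-validation driver. Per repeat: stratified
# k-fold partition; per fold, one base classifier per planned slice is
# trained on the training partition (augmented slices included, originals
# only elsewhere); classifiers are scored on the disjoint validation cohort;
# slices are ranked per axis by mean validation accuracy across the
# repeat's folds; each fold's ensemble of that repeat's selected slices
# votes on the fold's held-out subjects; pooled per-repeat predictions give
# the metrics; the selected coordinates give the repeat's intersection
# points for region counting.

#' Stratified k-fold plans with repeats
#'
#' Within each repeat the test folds partition the cohort; per-class fold
#' sizes follow a largest-remainder allocation (each class splits into folds
#' of size floor(n_c/k) with remainders assigned to the folds whose running
#' totals are smallest, processing classes from largest to smallest), so
#' class proportions per fold are within one subject of the cohort's.
#'
#' @param labels integer 0/1 vector (one per subject).
#' @param k folds (each class needs >= k members).
#' @param repeats number of independent shuffles.
#' @param seed integer seed; the plan is deterministic given (labels, k,
#'   repeats, seed).
#' @return an object of class `cnnel_folds`: tibble (repeat_id, fold, index)
#'   where `index` is the subject position and `fold` its test fold.
#' @export
make_stratified_folds <- function(labels, k = 5, repeats = 10, seed = 1) {
  labels <- as.integer(labels)
  counts <- table(labels)
  if (any(counts < k)) {
    rlang::abort(sprintf("class %s has %d members, fewer than k = %d",
                         names(counts)[which.min(counts)], min(counts), k))
  }
  plans <- purrr::map(seq_len(repeats), function(r) {
    totals <- numeric(k)
    fold_of <- integer(length(labels))
    classes <- names(sort(counts, decreasing = TRUE))
    for (cl in classes) {
      members <- which(labels == as.integer(cl))
      members <- with_seed(derive_seed(seed, 29L, r, as.integer(cl)),
                           sample(members))
      n_c <- length(members)
      sizes <- rep(n_c %/% k, k)
      rem <- n_c - sum(sizes)
      if (rem > 0) {
        extra <- order(totals, seq_len(k))[seq_len(rem)]
        sizes[extra] <- sizes[extra] + 1L
      }
      fold_of[members] <- rep(seq_len(k), times = sizes)
      totals <- totals + sizes
    }
    tibble::tibble(repeat_id = r, fold = fold_of,
                   index = seq_along(labels))
  })
  structure(dplyr::bind_rows(plans),
            k = as.integer(k), repeats = as.integer(repeats),
            class = c("cnnel_folds", class(tibble::tibble())))
}

#' Run the full slice-train-select-vote-localize experiment
#'
#' @param cohort training/testing `cnnel_cohort`.
#' @param validation disjoint `cnnel_cohort` used only to rank base
#'   classifiers.
#' @param atlas `cnnel_atlas` for region counting.
#' @param plan [slice_plan()]; defaults to the proportional plan for the
#'   cohort grid.
#' @param augment [augment_plan()] applied to training partitions, or `NULL`
#'   to skip augmentation.
#' @param config [train_config()].
#' @param ensemble [ensemble_config()].
#' @param repeats,k cross-validation protocol.
#' @param seed master seed; every random draw derives from (seed, repeat,
#'   fold, slice).
#' @param workers parallel workers for classifier training
#'   (`parallel::mclapply`); results are identical to serial execution
#'   because each training job derives its own seed.
#' @return an object of class `cnnel_experiment`: per-repeat `metrics`,
#'   `summary` (mean and n-1 sd per metric), `selected` slice records,
#'   `points`, `regions` ([count_regions()] over all repeats), and the
#'   configuration.
#' @export
run_experiment <- function(cohort, validation, atlas, plan = NULL,
                           augment = NULL, config = train_config(),
                           ensemble = ensemble_config(), repeats = 10,
                           k = 5, seed = 1, workers = 1) {
  stopifnot(inherits(cohort, "cnnel_cohort"), inherits(validation, "cnnel_cohort"))
  overlap <- intersect(cohort$info$subject_id, validation$info$subject_id)
  if (length(overlap) > 0) {
    rlang::abort(sprintf("leakage: subject(s) %s appear in both cohort and validation",
                         paste(head(overlap, 5), collapse = ", ")))
  }
  plan <- plan %||% slice_plan(dim(cohort$volumes[[1]]$grid),
                               cohort$volumes[[1]]$affine)
  t0 <- Sys.time()
  slices <- build_slice_dataset(cohort, plan)
  val_slices <- build_slice_dataset(validation, plan)
  folds <- make_stratified_folds(cohort$info$label, k = k, repeats = repeats,
                                 seed = seed)
  slice_keys <- dplyr::distinct(plan$coords, .data$axis, .data$mm)
  repeat_results <- purrr::map(seq_len(repeats), function(r) {
    fold_of <- folds$fold[folds$repeat_id == r]
    fold_classifiers <- purrr::map(seq_len(k), function(f) {
      test_ids <- cohort$info$subject_id[fold_of == f]
      train_rows <- slices[!slices$subject_id %in% test_ids, ]
      if (!is.null(augment)) {
        aug <- augment
        aug$seed <- derive_seed(seed, 41L, r, f)
        train_rows <- build_augmented_dataset(train_rows, aug)
      }
      groups <- dplyr::group_split(dplyr::group_by(train_rows, .data$axis,
                                                   .data$mm))
      train_one <- function(g) {
        cfg <- config
        cfg$seed <- derive_seed(seed, 43L, r, f,
                                axis_dim(as.character(g$axis[1])),
                                round(g$mm[1] * 100))
        train_classifier(g, cfg)
      }
      clfs <- if (workers > 1) {
        parallel::mclapply(groups, train_one, mc.cores = workers)
      } else {
        lapply(groups, train_one)
      }
      # validation accuracy per classifier
      scored <- purrr::map(clfs, function(clf) {
        rows <- val_slices[as.character(val_slices$axis) == clf$axis &
                             abs(val_slices$mm - clf$mm) < 1e-6, ]
        p <- predict_proba(clf, rows$image)
        clf$val_accuracy <- mean(max.col(p) - 1L == as.integer(rows$label))
        clf
      })
      names(scored) <- vapply(scored, function(c) paste(c$axis, signif(c$mm, 10)), "")
      scored
    })
    # rank slices by mean validation accuracy across this repeat's folds
    val_tbl <- dplyr::bind_rows(purrr::imap(fold_classifiers, function(clfs, f) {
      tibble::tibble(fold = f,
                     axis = vapply(clfs, `[[`, "", "axis"),
                     mm = vapply(clfs, `[[`, 0, "mm"),
                     val_accuracy = vapply(clfs, `[[`, 0, "val_accuracy"))
    }))
    mean_val <- dplyr::summarise(
      dplyr::group_by(val_tbl, .data$axis, .data$mm),
      val_accuracy = mean(.data$val_accuracy), .groups = "drop")
    selected <- rank_classifiers(
      dplyr::mutate(mean_val, axis = factor(.data$axis, levels = axis_levels())),
      ensemble$n_top)
    # per fold, vote on the held-out subjects with this repeat's selection
    preds <- purrr::map(seq_len(k), function(f) {
      test_ids <- cohort$info$subject_id[fold_of == f]
      test_rows <- slices[slices$subject_id %in% test_ids, ]
      member_tbl <- dplyr::mutate(
        selected,
        classifier = purrr::map2(as.character(.data$axis), .data$mm, function(a, m)
          fold_classifiers[[f]][[paste(a, signif(m, 10))]]))
      ens <- structure(list(members = member_tbl, config = ensemble),
                       class = "cnnel_ensemble")
      vote(ens, test_rows)
    })
    pooled <- dplyr::bind_rows(preds)
    metrics <- compute_metrics(pooled$label, pooled$pred, pooled$score)
    pts <- intersection_points(
      split(selected$mm, selected$axis), repeat_id = r)
    list(metrics = dplyr::mutate(metrics, repeat_id = r, .before = 1),
         selected = dplyr::mutate(tibble::as_tibble(selected[, c("axis", "mm", "val_accuracy", "rank")]),
                                  repeat_id = r, .before = 1),
         points = pts,
         predictions = dplyr::mutate(pooled, repeat_id = r, .before = 1))
  })
  metrics <- dplyr::bind_rows(purrr::map(repeat_results, "metrics"))
  points <- dplyr::bind_rows(purrr::map(repeat_results, "points"))
  regions <- count_regions(points, atlas)
  res <- structure(list(
    metrics = metrics,
    summary = aggregate_metrics(metrics),
    selected = dplyr::bind_rows(purrr::map(repeat_results, "selected")),
    predictions = dplyr::bind_rows(purrr::map(repeat_results, "predictions")),
    points = points,
    regions = regions,
    plan = plan,
    config = list(train = config, ensemble = ensemble, augment = augment,
                  repeats = repeats, k = k, seed = seed),
    runtime_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "cnnel_experiment")
  res
}

#' Aggregate per-repeat metrics
#'
#' Sample mean and sample standard deviation (n-1 denominator) per metric.
#' A single repeat reports sd 0 with a `single_repeat` caveat attribute.
#'
#' @param metrics tibble with per-repeat accuracy, auc, mcc.
#' @return tibble: metric, mean, sd, n_repeats.
#' @export
aggregate_metrics <- function(metrics) {
  assert_that(nrow(metrics) >= 1, "need at least one repeat")
  long <- tidyr::pivot_longer(metrics[, c("accuracy", "auc", "mcc")],
                              dplyr::everything(),
                              names_to = "metric", values_to = "value")
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$metric),
    mean = mean(.data$value, na.rm = TRUE),
    sd = if (dplyr::n() > 1) sd(.data$value, na.rm = TRUE) else 0,
    n_repeats = dplyr::n(), .groups = "drop")
  out <- out[match(c("accuracy", "auc", "mcc"), out$metric), ]
  if (nrow(metrics) == 1) attr(out, "single_repeat") <- TRUE
  out
}

#' @export
print.cnnel_experiment <- function(x, ...) {
  cat(sprintf("<cnnel_experiment> %d repeat(s) x %d folds, %d ensemble members each\n",
              x$config$repeats, x$config$k, 3 * x$config$ensemble$n_top))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-8s %.3f +/- %.3f\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  cat(sprintf("  %d intersection points, %d in labeled regions; top region: %s\n",
              attr(x$regions, "total_points"),
              attr(x$regions, "total_points") - attr(x$regions, "unlabeled_count"),
              if (nrow(x$regions) > 0) x$regions$name[1] else "none"))
  invisible(x)
}
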