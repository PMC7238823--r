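# Two-stage ensembling: per axis, keep the N base classifiers with the best
# held-out validation accuracy; an axis ensemble is the majority vote of its
# N members, and the three-axis ensemble is the majority vote of the three
# axis labels. With N odd the vote can never tie. A flat vote over all 3N
# members is available as an alternative reading.

#' Ensemble configuration
#'
#' @param n_top classifiers kept per axis (odd, default 5).
#' @param voting `"hierarchical"` (axis majorities, then across axes) or
#'   `"flat"` (single majority over all 3N members).
#' @return an object of class `cnnel_ensemble_config`.
#' @export
ensemble_config <- function(n_top = 5, voting = c("hierarchical", "flat")) {
  assert_that(n_top >= 1 && n_top %% 2 == 1, "n_top must be odd (tie-free axis vote)")
  structure(list(n_top = as.integer(n_top), voting = match.arg(voting)),
            class = "cnnel_ensemble_config")
}

# Shared ranking rule: validation accuracy descending, ties broken by
# smaller |MNI coordinate| (prefer central slices), then coordinate value.
rank_classifiers <- function(tbl, n_top) {
  ranked <- dplyr::arrange(
    dplyr::group_by(tbl, .data$axis),
    dplyr::desc(.data$val_accuracy), abs(.data$mm), .data$mm,
    .by_group = TRUE)
  ranked <- dplyr::slice_head(ranked, n = n_top)
  ranked <- dplyr::mutate(ranked, rank = dplyr::row_number())
  dplyr::ungroup(ranked)
}

#' Select the best-generalizing base classifiers per axis
#'
#' Scores every classifier by accuracy on the validation slices at its own
#' (axis, coordinate), keeps the top `n_top` per axis (ties broken by
#' smaller absolute MNI coordinate), and errors if any validation subject
#' overlaps a classifier's training subjects (leakage guard).
#'
#' @param classifiers list of trained [train_classifier()] objects.
#' @param validation a `cnnel_slices` dataset of held-out subjects
#'   (provenance `"original"` only).
#' @param config an [ensemble_config()].
#' @return an object of class `cnnel_ensemble`: tibble `members` (axis,
#'   mm, val_accuracy, rank, classifier list column) plus the config.
#' @export
select_top <- function(classifiers, validation, config = ensemble_config()) {
  assert_that(all(validation$provenance == "original"),
              "validation slices must be original (non-augmented)")
  val_ids <- unique(validation$subject_id)
  for (clf in classifiers) {
    overlap <- intersect(val_ids, clf$train_subjects)
    if (length(overlap) > 0) {
      rlang::abort(sprintf(
        "leakage: validation subject(s) %s were used to train the %s slice at %.6g mm",
        paste(overlap, collapse = ", "), clf$axis, clf$mm))
    }
  }
  scored <- purrr::map(classifiers, function(clf) {
    rows <- validation[as.character(validation$axis) == clf$axis &
                         abs(validation$mm - clf$mm) < 1e-6, ]
    assert_that(nrow(rows) > 0, sprintf(
      "validation set has no slices for %s at %.6g mm", clf$axis, clf$mm))
    p <- predict_proba(clf, rows$image)
    clf$val_accuracy <- mean(max.col(p) - 1L == as.integer(rows$label))
    clf
  })
  tbl <- tibble::tibble(
    axis = vapply(scored, `[[`, "", "axis"),
    mm = vapply(scored, `[[`, 0, "mm"),
    val_accuracy = vapply(scored, `[[`, 0, "val_accuracy"),
    classifier = scored)
  build_ensemble(tbl, config)
}

# Assemble an ensemble from a scored classifier table (axis, mm,
# val_accuracy, classifier).
build_ensemble <- function(tbl, config) {
  tbl$axis <- factor(tbl$axis, levels = axis_levels())
  n_axis <- table(tbl$axis)
  if (any(n_axis < config$n_top)) {
    short <- names(n_axis)[n_axis < config$n_top][1]
    rlang::abort(sprintf("only %d %s classifiers available but n_top = %d",
                         n_axis[[short]], short, config$n_top))
  }
  dup <- dplyr::summarise(dplyr::group_by(tbl, .data$axis),
                          dup = anyDuplicated(.data$mm) > 0)
  assert_that(!any(dup$dup), "member slice coordinates must be unique within an axis")
  members <- rank_classifiers(tbl, config$n_top)
  structure(list(members = members, config = config), class = "cnnel_ensemble")
}

#' @export
print.cnnel_ensemble <- function(x, ...) {
  cat(sprintf("<cnnel_ensemble> %d members (%d per axis), %s voting\n",
              nrow(x$members), x$config$n_top, x$config$voting))
  m <- dplyr::summarise(dplyr::group_by(x$members, .data$axis),
                        coords = paste(signif(.data$mm, 4), collapse = ", "),
                        acc = mean(.data$val_accuracy))
  for (i in seq_len(nrow(m))) {
    cat(sprintf("  %-10s [%s] mean validation accuracy %.3f\n",
                m$axis[i], m$coords[i], m$acc[i]))
  }
  invisible(x)
}

#' Combine member labels by majority vote
#'
#' Pure voting rule, exposed for direct use: `labels` holds one 0/1 label
#' per member and `axis` the member's slice family. Hierarchical voting
#' takes the majority within each axis and then the majority of the three
#' axis labels; flat voting takes a single majority over all members.
#'
#' @param labels integer vector of member labels (0/1).
#' @param axis character/factor vector of member axes (3 families).
#' @param voting `"hierarchical"` or `"flat"`.
#' @return the ensemble label (0 or 1).
#' @export
majority_vote <- function(labels, axis, voting = c("hierarchical", "flat")) {
  voting <- match.arg(voting)
  if (voting == "flat") {
    return(as.integer(mean(labels) > 0.5))
  }
  axis_lab <- tapply(labels, factor(as.character(axis), levels = axis_levels()),
                     function(v) as.integer(mean(v) > 0.5))
  axis_lab <- axis_lab[!is.na(axis_lab)]   # tolerate absent slice families
  as.integer(mean(axis_lab) > 0.5)
}

#' Predict subjects with a classifier ensemble
#'
#' Every member classifies its own slice of each subject; labels are
#' combined by [majority_vote()] and the continuous score is the mean
#' positive-class probability over all members (used for AUC).
#'
#' @param ensemble a `cnnel_ensemble`.
#' @param slices a `cnnel_slices` dataset containing, for every subject,
#'   the slices at all member coordinates (provenance `"original"`).
#' @return tibble: subject_id, label (truth, if present), pred, score.
#' @export
vote <- function(ensemble, slices) {
  stopifnot(inherits(ensemble, "cnnel_ensemble"))
  assert_that(all(slices$provenance == "original"),
              "prediction slices must be original (non-augmented)")
  subjects <- unique(slices$subject_id)
  member_pred <- purrr::pmap(ensemble$members, function(axis, mm, val_accuracy,
                                                        rank, classifier) {
    rows <- slices[as.character(slices$axis) == as.character(axis) &
                     abs(slices$mm - mm) < 1e-6, ]
    missing <- setdiff(subjects, rows$subject_id)
    if (length(missing) > 0) {
      rlang::abort(sprintf("missing slice (%s, %.6g mm) for subject(s): %s",
                           axis, mm, paste(head(missing, 5), collapse = ", ")))
    }
    rows <- rows[match(subjects, rows$subject_id), ]
    p <- predict_proba(classifier, rows$image)
    tibble::tibble(axis = as.character(axis), subject_id = subjects,
                   member_label = max.col(p) - 1L, p1 = p[, 2])
  })
  mp <- dplyr::bind_rows(member_pred)
  per_subj <- dplyr::summarise(
    dplyr::group_by(mp, .data$subject_id),
    pred = majority_vote(.data$member_label, .data$axis,
                         ensemble$config$voting),
    score = mean(.data$p1))
  out <- per_subj[match(subjects, per_subj$subject_id), ]
  if ("label" %in% names(slices)) {
    truth <- slices$label[match(subjects, slices$subject_id)]
    out <- dplyr::mutate(out, label = as.integer(truth), .after = "subject_id")
  }
  out
}

#' Classification performance metrics
#'
#' Accuracy, rank-based AUC (mid-rank tie handling) and the Matthews
#' correlation coefficient from the confusion matrix. With single-class
#' truth, AUC and MCC are undefined and returned as `NA`.
#'
#' @param truth integer 0/1 true labels.
#' @param pred integer 0/1 predicted labels.
#' @param score numeric positive-class scores (for AUC); optional.
#' @return one-row tibble: accuracy, auc, mcc, n.
#' @export
compute_metrics <- function(truth, pred, score = NULL) {
  assert_that(length(truth) == length(pred), "truth and pred lengths differ")
  truth <- as.integer(truth); pred <- as.integer(pred)
  acc <- mean(truth == pred)
  if (length(unique(truth)) < 2) {
    return(tibble::tibble(accuracy = acc, auc = NA_real_, mcc = NA_real_,
                          n = length(truth)))
  }
  tp <- sum(truth == 1 & pred == 1); tn <- sum(truth == 0 & pred == 0)
  fp <- sum(truth == 0 & pred == 1); fn <- sum(truth == 1 & pred == 0)
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (denom == 0) NA_real_ else (tp * tn - fp * fn) / denom
  auc <- NA_real_
  if (!is.null(score)) {
    r <- rank(score)                     # mid-ranks for ties
    n1 <- sum(truth == 1); n0 <- sum(truth == 0)
    auc <- (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  tibble::tibble(accuracy = acc, auc = auc, mcc = mcc, n = length(truth))
}

#' Compare two accuracy distributions
#'
#' Two-sided two-sample t-test whose variance treatment is chosen by an F
#' test of variance homogeneity at the 0.05 level: pooled variance if
#' homogeneity holds, unequal-variance (Welch) correction otherwise.
#'
#' @param a,b numeric vectors of per-repeat accuracies (length >= 2 each).
#' @return the two-sided p-value, with attributes `welch` (logical) and
#'   `statistic`.
#' @export
compare_accuracy_distributions <- function(a, b) {
  assert_that(length(a) >= 2 && length(b) >= 2, "need at least 2 values per sample")
  if (var(a) == 0 && var(b) == 0) {
    p <- if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
    return(structure(p, welch = FALSE, statistic = if (p == 1) 0 else Inf))
  }
  welch <- FALSE
  if (var(a) > 0 && var(b) > 0) {
    welch <- stats::var.test(a, b)$p.value < 0.05
  } else {
    welch <- TRUE                        # one-sided degeneracy: be conservative
  }
  tt <- stats::t.test(a, b, var.equal = !welch)
  structure(unname(tt$p.value), welch = welch,
            statistic = unname(tt$statistic))
}
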