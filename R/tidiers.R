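# broom-style tidiers and ggplot2 methods for the fitted objects.

#' @describeIn tidiers per-repeat metrics, one row per repeat.
#' @param x a `cnnel_experiment`.
#' @param ... unused.
#' @export
tidy.cnnel_experiment <- function(x, ...) {
  x$metrics
}

#' @describeIn tidiers one-row experiment summary (metric means and sds,
#'   protocol sizes, top region).
#' @export
glance.cnnel_experiment <- function(x, ...) {
  s <- x$summary
  g <- tibble::tibble(
    accuracy = s$mean[s$metric == "accuracy"],
    accuracy_sd = s$sd[s$metric == "accuracy"],
    auc = s$mean[s$metric == "auc"],
    auc_sd = s$sd[s$metric == "auc"],
    mcc = s$mean[s$metric == "mcc"],
    mcc_sd = s$sd[s$metric == "mcc"],
    repeats = x$config$repeats, k = x$config$k,
    n_members = 3L * x$config$ensemble$n_top,
    total_points = attr(x$regions, "total_points"),
    unlabeled_points = attr(x$regions, "unlabeled_count"),
    top_region = if (nrow(x$regions) > 0) x$regions$name[1] else NA_character_)
  g
}

#' @describeIn tidiers ensemble members (axis, coordinate, validation
#'   accuracy, rank).
#' @export
tidy.cnnel_ensemble <- function(x, ...) {
  tibble::as_tibble(x$members[, c("axis", "mm", "val_accuracy", "rank")])
}

#' @describeIn tidiers one-row ensemble summary.
#' @export
glance.cnnel_ensemble <- function(x, ...) {
  tibble::tibble(n_members = nrow(x$members),
                 n_top = x$config$n_top,
                 voting = x$config$voting,
                 mean_val_accuracy = mean(x$members$val_accuracy))
}

#' @describeIn tidiers per-epoch training history of a base classifier.
#' @export
tidy.cnnel_classifier <- function(x, ...) {
  dplyr::mutate(x$history, axis = x$axis, mm = x$mm)
}

#' Tidiers for fitted objects
#'
#' @name tidiers
NULL

#' Plot per-repeat metric distributions of an experiment
#'
#' @param object a `cnnel_experiment`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.cnnel_experiment <- function(object, ...) {
  long <- tidyr::pivot_longer(object$metrics,
                              c("accuracy", "auc", "mcc"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "per-repeat value",
                  title = "Held-out performance across repeats") +
    ggplot2::theme_minimal()
}

#' Plot a region count table
#'
#' Horizontal bar chart of intersection-point counts per region, the
#' standard display for the localization result.
#'
#' @param object a `cnnel_regions` table.
#' @param max_regions show at most this many top regions.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.cnnel_regions <- function(object, max_regions = 20, ...) {
  tab <- utils::head(tibble::as_tibble(object), max_regions)
  tab$name <- factor(tab$name, levels = rev(unique(tab$name)))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$n_points, y = .data$name)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "# intersection points", y = NULL,
                  title = "Discriminable regions by intersection-point count") +
    ggplot2::theme_minimal()
}

#' Plot the training history of a base classifier
#'
#' @param object a `cnnel_classifier`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.cnnel_classifier <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history, c("loss", "accuracy"),
                              names_to = "series", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::labs(title = sprintf("%s slice at %.4g mm", object$axis, object$mm)) +
    ggplot2::theme_minimal()
}
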