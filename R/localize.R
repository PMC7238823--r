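# Data-driven localization: the N selected slices per axis define N^3
# intersection points in MNI space; each point's atlas label is a vote for
# that region's discriminability, accumulated over cross-validation repeats.

#' Intersection points of an ensemble's selected slices
#'
#' Cartesian product of the selected sagittal x coronal x transverse slice
#' coordinates: exactly `n_top^3` distinct points, in lexicographic (x, y,
#' z) order.
#'
#' @param model a `cnnel_ensemble`, or a named list
#'   `list(sagittal =, coronal =, transverse =)` of mm coordinate vectors.
#' @param repeat_id optional repeat identifier carried into the output.
#' @return tibble with columns x, y, z (and `repeat_id` if given).
#' @export
intersection_points <- function(model, repeat_id = NULL) {
  coords <- if (inherits(model, "cnnel_ensemble")) {
    split(model$members$mm, model$members$axis)
  } else {
    model
  }
  xs <- sort(coords$sagittal); ys <- sort(coords$coronal)
  zs <- sort(coords$transverse)
  assert_that(length(xs) > 0 && length(ys) > 0 && length(zs) > 0,
              "need selected coordinates on all three axes")
  pts <- expand.grid(z = zs, y = ys, x = xs)   # x slowest => lexicographic
  out <- tibble::tibble(x = pts$x, y = pts$y, z = pts$z)
  if (!is.null(repeat_id)) out$repeat_id <- repeat_id
  out
}

#' Atlas label at MNI points
#'
#' Maps points through the inverse atlas affine and rounds to the nearest
#' voxel index (halfway ties toward negative infinity). Points outside the
#' grid, or on label 0, are unlabeled (0).
#'
#' @param points tibble/matrix with x, y, z in mm (one row per point), or a
#'   length-3 vector for a single point.
#' @param atlas a `cnnel_atlas`.
#' @return integer vector of labels (0 = unlabeled).
#' @export
point_to_label <- function(points, atlas) {
  stopifnot(inherits(atlas, "cnnel_atlas"))
  if (is.numeric(points) && is.null(dim(points))) points <- matrix(points, ncol = 3)
  if (is.data.frame(points)) points <- as.matrix(points[, c("x", "y", "z")])
  vox <- world_to_voxel(points, atlas$affine)
  idx <- round_half_down(vox)
  shape <- dim(atlas$label_grid)
  inside <- idx[, 1] >= 0 & idx[, 1] < shape[1] &
    idx[, 2] >= 0 & idx[, 2] < shape[2] &
    idx[, 3] >= 0 & idx[, 3] < shape[3]
  labels <- integer(nrow(idx))
  if (any(inside)) {
    labels[inside] <- atlas$label_grid[idx[inside, , drop = FALSE] + 1L]
  }
  labels
}

#' Count intersection points per atlas region
#'
#' Sums, over all repeats, the number of intersection points falling in each
#' labeled region. Conservation always holds: labeled counts plus the
#' unlabeled count equal the total number of points.
#'
#' @param points tibble of intersection points (rows from one or more
#'   repeats, e.g. bound [intersection_points()] outputs).
#' @param atlas a `cnnel_atlas`.
#' @return an object of class `cnnel_regions`: tibble (label, name,
#'   n_points) sorted by count descending, restricted to labels with a
#'   positive count, with attributes `total_points` and `unlabeled_count`.
#' @export
count_regions <- function(points, atlas) {
  labels <- point_to_label(points, atlas)
  tab <- table(labels[labels > 0])
  out <- tibble::tibble(
    label = as.integer(names(tab)),
    name = unname(atlas$names[names(tab)]),
    n_points = as.integer(tab))
  out <- dplyr::arrange(out, dplyr::desc(.data$n_points), .data$label)
  structure(out, total_points = length(labels),
            unlabeled_count = sum(labels == 0),
            class = c("cnnel_regions", class(out)))
}

#' @export
print.cnnel_regions <- function(x, n = 10, ...) {
  cat(sprintf("<cnnel_regions> %d points, %d in %d labeled regions, %d unlabeled\n",
              attr(x, "total_points"),
              attr(x, "total_points") - attr(x, "unlabeled_count"),
              nrow(x), attr(x, "unlabeled_count")))
  print(tibble::as_tibble(x), n = n)
  invisible(x)
}

#' Behavioral-domain histogram of identified regions
#'
#' Counts, per behavioral domain, how many distinct regions with at least
#' one intersection point carry that domain tag. A region with several tags
#' increments each of them; regions absent from the lookup are grouped
#' under `"unknown"`.
#'
#' @param regions a [count_regions()] table.
#' @param domains named list (label -> character vector of domain tags),
#'   e.g. the `domains` field of a `cnnel_atlas`.
#' @return tibble: domain, n_regions, sorted descending.
#' @export
domain_histogram <- function(regions, domains) {
  if (nrow(regions) == 0) {
    return(tibble::tibble(domain = character(), n_regions = integer()))
  }
  tags <- lapply(as.character(regions$label), function(l) {
    d <- domains[[l]]
    if (is.null(d) || length(d) == 0) "unknown" else unique(d)
  })
  tab <- table(unlist(tags))
  out <- tibble::tibble(domain = names(tab), n_regions = as.integer(tab))
  dplyr::arrange(out, dplyr::desc(.data$n_regions), .data$domain)
}

#' Write a region count table as TSV
#'
#' @param regions a [count_regions()] table.
#' @param path output TSV path (columns label, name, n_points).
#' @return `path`, invisibly.
#' @export
write_region_table <- function(regions, path) {
  readr::write_tsv(tibble::as_tibble(regions), path)
  invisible(path)
}
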