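# Slice planning and extraction. A slice plan enumerates, per anatomical
# axis, the voxel indices (every 2nd index inside a crop window, i.e. every
# other 1.5 mm slice = 3 mm stride) whose orthogonal planes feed the base
# classifiers, together with their MNI mm coordinates derived from the
# affine. End-of-axis slices carry little discriminative tissue and are
# cropped away. On the full 121 x 145 x 121 grid the default windows give
# 40 sagittal, 50 coronal and 33 transverse positions (123 in total);
# scaled-down grids shrink the windows proportionally so small synthetic
# volumes traverse identical code paths.

# Full-scale crop windows, as 0-based voxel index ranges per axis.
full_crop_index <- function() {
  list(sagittal = c(19L, 97L), coronal = c(23L, 121L), transverse = c(29L, 93L))
}

#' Build a slice plan for a volume grid
#'
#' @param shape 3 voxel counts of the target volumes.
#' @param affine voxel-to-world matrix; defaults to [mni_affine()] of `shape`.
#' @param crop optional named list (`sagittal`, `coronal`, `transverse`) of
#'   `c(min, max)` MNI mm crop windows. When omitted, the full-scale windows
#'   are scaled proportionally to `shape`.
#' @param step index stride between consecutive slices (default 2 voxels,
#'   i.e. every other slice).
#' @return an object of class `cnnel_slice_plan`: list with `shape`,
#'   `affine`, `side` (square network input side, the largest grid
#'   dimension) and `coords` (tibble: axis, index, mm).
#' @export
slice_plan <- function(shape, affine = mni_affine(shape), crop = NULL,
                       step = 2L) {
  shape <- as.integer(shape)
  assert_that(length(shape) == 3 && all(shape > 0), "shape must be 3 positive counts")
  full <- c(121L, 145L, 121L)
  rows <- list()
  for (a in seq_along(axis_levels())) {
    axis <- axis_levels()[a]
    if (is.null(crop)) {
      w <- full_crop_index()[[axis]]
      lo <- as.integer(round_half_up(w[1] * (shape[a] - 1) / (full[a] - 1)))
      hi <- as.integer(round_half_up(w[2] * (shape[a] - 1) / (full[a] - 1)))
    } else {
      w <- crop[[axis]]
      assert_that(!is.null(w) && length(w) == 2, sprintf("crop$%s must be c(min, max) in mm", axis))
      # mm -> voxel index along this axis
      origin <- affine[a, 4]; sp <- affine[a, a]
      lo <- as.integer(ceiling((w[1] - origin) / sp - 1e-9))
      hi <- as.integer(floor((w[2] - origin) / sp + 1e-9))
      if (lo < 0 || hi > shape[a] - 1 || lo > hi) {
        rlang::abort(sprintf("crop window for %s axis lies outside the volume extent", axis))
      }
    }
    idx <- seq.int(lo, hi, by = step)
    mm <- affine[a, a] * idx + affine[a, 4]
    rows[[axis]] <- tibble::tibble(axis = axis, index = as.integer(idx), mm = mm)
  }
  coords <- dplyr::bind_rows(rows)
  coords$axis <- factor(coords$axis, levels = axis_levels())
  structure(list(shape = shape, affine = affine, side = max(shape),
                 step = as.integer(step), coords = coords),
            class = "cnnel_slice_plan")
}

#' @export
print.cnnel_slice_plan <- function(x, ...) {
  n <- table(x$coords$axis)
  cat(sprintf("<cnnel_slice_plan> grid %s, side %d: %d sagittal + %d coronal + %d transverse = %d slices\n",
              paste(x$shape, collapse = " x "), x$side,
              n[["sagittal"]], n[["coronal"]], n[["transverse"]],
              nrow(x$coords)))
  invisible(x)
}

#' Slice coordinates of a plan along one axis
#'
#' @param plan a [slice_plan()].
#' @param axis `"sagittal"`, `"coronal"` or `"transverse"`.
#' @return increasing numeric vector of MNI mm coordinates with constant
#'   stride (`step` voxels times the spacing).
#' @export
select_slice_coordinates <- function(plan, axis) {
  stopifnot(inherits(plan, "cnnel_slice_plan"))
  axis <- match.arg(axis, axis_levels())
  sort(plan$coords$mm[plan$coords$axis == axis])
}

#' Extract one orthogonal 2D slice from a volume
#'
#' The coordinate is mapped through the inverse affine and must land on an
#' integer voxel index within `tol` voxels. In-plane orientation: a sagittal
#' slice is returned as Y x Z, a coronal slice as X x Z, and a transverse
#' slice as X x Y, with rows/columns in increasing MNI coordinate order.
#'
#' @param volume a `cnnel_volume`.
#' @param axis slice orientation.
#' @param coord MNI mm coordinate along the orthogonal axis.
#' @param tol voxel-index tolerance (default 0.25).
#' @return a 2D numeric matrix.
#' @export
extract_slice <- function(volume, axis, coord, tol = 0.25) {
  stopifnot(inherits(volume, "cnnel_volume"))
  a <- axis_dim(axis)
  idx <- (coord - volume$affine[a, 4]) / volume$affine[a, a]
  i <- round(idx)
  if (abs(idx - i) > tol || i < 0 || i > dim(volume$grid)[a] - 1) {
    near <- min(max(round(idx), 0), dim(volume$grid)[a] - 1)
    rlang::abort(sprintf(
      "no %s grid slice at %.6g mm; nearest grid coordinate is %.6g mm",
      match.arg(axis, axis_levels()), coord,
      volume$affine[a, a] * near + volume$affine[a, 4]))
  }
  switch(a,
         volume$grid[i + 1, , ],
         volume$grid[, i + 1, ],
         volume$grid[, , i + 1])
}

#' Pad a 2D slice to a square
#'
#' Centers the content in an S x S frame (any parity-induced off-by-one
#' goes to the high-index side). Margin rows/columns within `edge_margin`
#' voxels of the content replicate the nearest edge; anything farther out is
#' zero-filled. Original intensities are never altered.
#'
#' @param image 2D numeric matrix, both dimensions <= `side`.
#' @param side target side length S.
#' @param edge_margin width (in voxels) of the edge-replication band
#'   (default 4); set 0 for pure zero-fill.
#' @return an S x S matrix.
#' @export
pad_to_square <- function(image, side, edge_margin = 4L) {
  assert_that(is.matrix(image), "image must be a 2D matrix")
  d <- dim(image)
  if (any(d > side)) {
    rlang::abort(sprintf("image (%d x %d) larger than target side %d",
                         d[1], d[2], side))
  }
  pad1 <- c((side - d[1]) %/% 2, side - d[1] - (side - d[1]) %/% 2)
  pad2 <- c((side - d[2]) %/% 2, side - d[2] - (side - d[2]) %/% 2)
  out <- matrix(0, side, side)
  r <- (pad1[1] + 1):(pad1[1] + d[1])
  cc <- (pad2[1] + 1):(pad2[1] + d[2])
  out[r, cc] <- image
  fill_band <- function(n_pad) {
    # distances 1..n_pad from the content edge; replicate within edge_margin
    if (n_pad == 0) return(integer())
    which(seq_len(n_pad) <= edge_margin)
  }
  # rows below / above content
  for (k in fill_band(pad1[1])) out[pad1[1] + 1 - k, cc] <- image[1, ]
  for (k in fill_band(pad1[2])) out[pad1[1] + d[1] + k, cc] <- image[d[1], ]
  # full columns left / right of content (replicate the padded column edge)
  left_edge <- out[, cc[1]]
  right_edge <- out[, cc[length(cc)]]
  for (k in fill_band(pad2[1])) out[, pad2[1] + 1 - k] <- left_edge
  for (k in fill_band(pad2[2])) out[, pad2[1] + d[2] + k] <- right_edge
  out
}

#' Build slice datasets for a cohort
#'
#' Normalizes every volume, extracts each planned slice and pads it to the
#' plan's square side. Returns one row per (axis, coordinate, subject) with
#' the image as a list column, provenance `"original"`.
#'
#' @param cohort a `cnnel_cohort`.
#' @param plan a [slice_plan()] matching the cohort grid.
#' @param normalize divide by the per-volume maximum first (default TRUE).
#' @return a tibble: axis, mm, subject_id, label, provenance, operation,
#'   image (list of side x side matrices). Class `cnnel_slices`, with the
#'   plan side kept in attribute `side`.
#' @export
build_slice_dataset <- function(cohort, plan, normalize = TRUE) {
  stopifnot(inherits(cohort, "cnnel_cohort"), inherits(plan, "cnnel_slice_plan"))
  assert_that(all(dim(cohort$volumes[[1]]$grid) == plan$shape),
              "plan shape does not match cohort volumes")
  vols <- cohort$volumes
  if (normalize) vols <- lapply(vols, normalize_intensity)
  rows <- purrr::pmap(plan$coords, function(axis, index, mm) {
    imgs <- lapply(vols, function(v)
      pad_to_square(extract_slice(v, as.character(axis), mm), plan$side))
    tibble::tibble(axis = as.character(axis), mm = mm,
                   subject_id = cohort$info$subject_id,
                   label = cohort$info$label,
                   provenance = "original", operation = NA_character_,
                   image = imgs)
  })
  out <- dplyr::bind_rows(rows)
  out$axis <- factor(out$axis, levels = axis_levels())
  structure(out, side = plan$side, class = c("cnnel_slices", class(out)))
}
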