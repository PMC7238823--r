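#' MNI-style affine for a (possibly scaled) analysis grid
#'
#' Builds the 4x4 voxel-to-world matrix used throughout the package: RAS+
#' axes, isotropic spacing, and an origin placed so the grid covers the same
#' relative window of MNI space as the full-resolution 121 x 145 x 121 grid
#' at 1.5 mm (whose voxel (0,0,0) sits at (-90, -126, -72) mm). Scaled-down
#' grids used for testing keep the 1.5 mm spacing and shrink the physical
#' extent proportionally, so every coordinate computation follows the same
#' code path as at full scale.
#'
#' @param shape integer vector of 3 voxel counts.
#' @param spacing isotropic voxel size in mm (default 1.5).
#' @return a 4x4 numeric matrix mapping 0-based voxel indices to MNI mm.
#' @export
mni_affine <- function(shape, spacing = 1.5) {
  shape <- as.integer(shape)
  assert_that(length(shape) == 3 && all(shape > 0), "shape must be 3 positive voxel counts")
  full <- c(121L, 145L, 121L)
  full_origin <- c(-90, -126, -72)
  origin <- full_origin * (shape - 1) / (full - 1) * spacing / 1.5
  aff <- diag(c(rep(spacing, 3), 1))
  aff[1:3, 4] <- origin
  aff
}

#' Construct a volume
#'
#' A volume is a 3D intensity grid plus the 4x4 affine mapping 0-based voxel
#' indices to MNI mm, and a subject identifier.
#'
#' @param grid 3D numeric array.
#' @param affine 4x4 voxel-to-world matrix; defaults to [mni_affine()] of the
#'   grid shape.
#' @param subject_id identifier string.
#' @return an object of class `cnnel_volume`.
#' @export
as_volume <- function(grid, affine = mni_affine(dim(grid)), subject_id = "subj") {
  assert_that(length(dim(grid)) == 3, "grid must be a 3D array")
  assert_that(all(is.finite(grid)), "grid must be finite")
  assert_that(is.matrix(affine) && all(dim(affine) == c(4, 4)),
              "affine must be a 4x4 matrix")
  assert_that(abs(det(affine)) > .Machine$double.eps, "affine must be invertible")
  structure(list(grid = grid, affine = affine, subject_id = subject_id),
            class = "cnnel_volume")
}

#' @export
print.cnnel_volume <- function(x, ...) {
  cat(sprintf("<cnnel_volume> %s  %s voxels, spacing %s mm, range [%.3g, %.3g]\n",
              x$subject_id, paste(dim(x$grid), collapse = " x "),
              paste(signif(abs(diag(x$affine)[1:3]), 3), collapse = "/"),
              min(x$grid), max(x$grid)))
  invisible(x)
}

# world mm (n x 3) -> 0-based fractional voxel indices
world_to_voxel <- function(points, affine) {
  points <- matrix(points, ncol = 3)
  inv <- solve(affine)
  t(inv %*% rbind(t(points), 1))[, 1:3, drop = FALSE]
}

# 0-based voxel indices (n x 3) -> world mm
voxel_to_world <- function(index, affine) {
  index <- matrix(index, ncol = 3)
  t(affine %*% rbind(t(index), 1))[, 1:3, drop = FALSE]
}

#' Normalize volume intensities to the unit interval
#'
#' Divides every voxel by the volume's maximum, the per-image intensity
#' normalization applied before slicing: values land in \[0, 1\] and at
#' least one voxel equals 1. Idempotent.
#'
#' @param volume a [as_volume()] object.
#' @return the volume with rescaled grid.
#' @export
normalize_intensity <- function(volume) {
  stopifnot(inherits(volume, "cnnel_volume"))
  m <- max(volume$grid)
  if (m <= 0) {
    rlang::abort("degenerate input: volume has no positive intensity to normalize")
  }
  volume$grid <- volume$grid / m
  volume
}

#' Write a volume to NIfTI
#'
#' @param volume a `cnnel_volume`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  img <- RNifti::asNifti(volume$grid, internal = FALSE)
  RNifti::pixdim(img) <- abs(diag(volume$affine)[1:3])
  RNifti::qform(img) <- structure(volume$affine, code = 2L)
  RNifti::sform(img) <- structure(volume$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume
#'
#' @param path NIfTI file path.
#' @param subject_id identifier to attach; defaults to the file stem.
#' @return a `cnnel_volume`.
#' @export
read_volume <- function(path, subject_id = NULL) {
  img <- RNifti::readNifti(path)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4, 4))
  sid <- subject_id %||% sub("\\.nii(\\.gz)?$", "", basename(path))
  as_volume(array(as.numeric(img), dim = dim(img)), aff, sid)
}
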