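# Synthetic MNI-like cohorts and atlases. The generator plants a class
# effect (a mean-intensity shift standing in for regional atrophy) inside
# chosen atlas regions on top of spatially smoothed noise over a fixed
# anatomical-looking template, so the whole pipeline -- slicing, training,
# selection, voting and region localization -- runs with no external data.

#' Generate a labeled synthetic atlas
#'
#' Builds a brain-like ellipsoidal mask on the given grid and tiles it into
#' `n_regions` connected blobs (Voronoi cells of seed points drawn inside
#' the mask). Voxels outside the mask carry label 0 (unlabeled). Regions are
#' named `region_01`, `region_02`, ... and each is tagged with one or two
#' behavioral-domain labels drawn from a small fixed vocabulary so that
#' domain histograms can be exercised.
#'
#' @param shape 3 voxel counts; default 24 x 28 x 24, a desk-scale grid with
#'   the same aspect ratio as the full 121 x 145 x 121 MNI grid.
#' @param n_regions number of labeled regions (>= 1).
#' @param seed integer seed; the atlas is deterministic given (shape,
#'   n_regions, seed).
#' @param spacing voxel size in mm.
#' @return an object of class `cnnel_atlas`: list with `label_grid` (3D
#'   integer array), `affine`, `names` (named character vector keyed by
#'   label) and `domains` (named list of character vectors keyed by label).
#' @export
make_atlas <- function(shape = c(24, 28, 24), n_regions = 6, seed = 1,
                       spacing = 1.5) {
  shape <- as.integer(shape)
  assert_that(length(shape) == 3 && all(shape > 0), "shape must be 3 positive counts")
  assert_that(n_regions >= 1, "n_regions must be >= 1")
  if (n_regions > prod(shape)) {
    rlang::abort("invalid argument: n_regions exceeds the number of voxels")
  }
  affine <- mni_affine(shape, spacing)
  mask <- brain_mask(shape)
  idx <- which(mask)
  assert_that(length(idx) >= n_regions, "mask too small for n_regions")
  coords <- arrayInd(idx, shape)
  seeds <- with_seed(derive_seed(seed, 101L), {
    coords[sample.int(nrow(coords), n_regions), , drop = FALSE]
  })
  seeds <- matrix(seeds, ncol = 3)
  # nearest-seed (Voronoi) labeling restricted to the mask: cells of a
  # Voronoi tessellation are convex, hence connected blobs
  d2 <- matrix(0, nrow(coords), n_regions)
  for (r in seq_len(n_regions)) {
    d2[, r] <- (coords[, 1] - seeds[r, 1])^2 +
      (coords[, 2] - seeds[r, 2])^2 +
      (coords[, 3] - seeds[r, 3])^2
  }
  lab <- max.col(-d2, ties.method = "first")
  label_grid <- array(0L, shape)
  label_grid[idx] <- lab
  labels <- seq_len(n_regions)
  names_vec <- sprintf("region_%02d", labels)
  names(names_vec) <- labels
  vocab <- c("memory", "emotion", "attention", "language", "executive")
  domains <- with_seed(derive_seed(seed, 202L), {
    lapply(labels, function(l) sample(vocab, sample(1:2, 1)))
  })
  names(domains) <- labels
  structure(list(label_grid = label_grid, affine = affine,
                 names = names_vec, domains = domains),
            class = "cnnel_atlas")
}

#' @export
print.cnnel_atlas <- function(x, ...) {
  cat(sprintf("<cnnel_atlas> %s voxels, %d regions, %d labeled voxels\n",
              paste(dim(x$label_grid), collapse = " x "),
              length(x$names), sum(x$label_grid > 0)))
  invisible(x)
}

# Smooth ellipsoidal "brain" template in [0,1]: an ellipsoid with a soft
# edge plus a broad interior intensity gradient, giving slices non-trivial
# structure without claiming anatomical realism.
brain_template <- function(shape) {
  shape <- as.integer(shape)
  ax <- lapply(shape, function(n) (seq_len(n) - (n + 1) / 2) / (n / 2))
  r2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  edge <- 1 / (1 + exp((sqrt(r2) - 0.85) / 0.05))
  interior <- 0.55 + 0.45 * exp(-r2 / 0.4)
  edge * interior
}

brain_mask <- function(shape) {
  brain_template(shape) > 0.25
}

# Separable Gaussian smoothing of a 3D array; fwhm in mm.
smooth_gaussian3d <- function(x, fwhm, spacing = 1.5) {
  if (fwhm <= 0) return(x)
  sigma <- fwhm / (2 * sqrt(2 * log(2))) / spacing   # voxels
  half <- max(1L, ceiling(3 * sigma))
  kern <- exp(-0.5 * ((-half:half) / sigma)^2)
  kern <- kern / sum(kern)
  d <- dim(x)
  for (axis in 1:3) {
    x <- apply(x, setdiff(1:3, axis), function(v) {
      vp <- c(rep(v[1], half), v, rep(v[length(v)], half))
      stats::filter(vp, kern, sides = 2)[(half + 1):(half + length(v))]
    })
    x <- aperm(array(x, dim = c(d[axis], d[setdiff(1:3, axis)])),
               order(c(axis, setdiff(1:3, axis))))
  }
  x
}

#' Specify the planted class effect
#'
#' @param region_labels atlas labels that carry the class effect (non-empty).
#' @param effect_size mean intensity shift inside the effect regions for
#'   class 1, expressed as a multiple of `noise_sd` (>= 0). 0 plants no
#'   signal (null cohort).
#' @param noise_sd standard deviation of the background Gaussian noise
#'   before smoothing, on the template's unit intensity scale (> 0).
#' @param smooth_fwhm full-width-at-half-maximum of the spatial smoothing
#'   applied to the noise field, in mm.
#' @return an object of class `cnnel_effect`.
#' @export
effect_spec <- function(region_labels, effect_size = 5, noise_sd = 0.05,
                        smooth_fwhm = 6) {
  assert_that(length(region_labels) >= 1, "region_labels must be non-empty")
  assert_that(effect_size >= 0, "effect_size must be >= 0")
  assert_that(noise_sd > 0, "noise_sd must be > 0")
  structure(list(region_labels = as.integer(region_labels),
                 effect_size = effect_size, noise_sd = noise_sd,
                 smooth_fwhm = smooth_fwhm),
            class = "cnnel_effect")
}

#' Simulate a two-class cohort of MNI-like volumes
#'
#' Each volume is the shared template plus subject-specific smoothed
#' Gaussian noise; volumes of class 1 additionally have the mean intensity
#' inside the effect regions shifted by `effect_size * noise_sd`. The
#' background is identically distributed between classes. One RNG substream
#' per subject, derived from `(seed, subject index)`, makes cohorts
#' reproducible under parallel generation.
#'
#' @param atlas a [make_atlas()] bundle (defines grid, affine and regions).
#' @param effect an [effect_spec()].
#' @param n_per_class counts `c(n_class0, n_class1)`.
#' @param seed integer seed.
#' @return an object of class `cnnel_cohort`: list with `volumes` (list of
#'   `cnnel_volume`) and `info` (tibble: subject_id, label).
#' @export
simulate_cohort <- function(atlas, effect, n_per_class = c(20, 20), seed = 1) {
  stopifnot(inherits(atlas, "cnnel_atlas"), inherits(effect, "cnnel_effect"))
  unknown <- setdiff(effect$region_labels, as.integer(names(atlas$names)))
  if (length(unknown) > 0) {
    rlang::abort(sprintf("unknown atlas label(s): %s",
                         paste(unknown, collapse = ", ")))
  }
  shape <- dim(atlas$label_grid)
  spacing <- abs(atlas$affine[1, 1])
  template <- brain_template(shape)
  region <- atlas$label_grid %in% effect$region_labels
  dim(region) <- shape
  n <- sum(n_per_class)
  labels <- rep(c(0L, 1L), n_per_class)
  shift <- effect$effect_size * effect$noise_sd
  volumes <- vector("list", n)
  for (s in seq_len(n)) {
    noise <- with_seed(derive_seed(seed, 7L, s),
                       array(rnorm(prod(shape), sd = effect$noise_sd), shape))
    noise <- smooth_gaussian3d(noise, effect$smooth_fwhm, spacing)
    grid <- template + noise
    if (labels[s] == 1L) grid[region] <- grid[region] + shift
    grid <- pmax(grid, 0)
    volumes[[s]] <- as_volume(grid, atlas$affine,
                              subject_id = sprintf("subj_%03d", s))
  }
  structure(list(volumes = volumes,
                 info = tibble::tibble(
                   subject_id = vapply(volumes, `[[`, "", "subject_id"),
                   label = labels)),
            class = "cnnel_cohort")
}

#' @export
print.cnnel_cohort <- function(x, ...) {
  cat(sprintf("<cnnel_cohort> %d subjects (%d / %d per class), grid %s\n",
              nrow(x$info), sum(x$info$label == 0), sum(x$info$label == 1),
              paste(dim(x$volumes[[1]]$grid), collapse = " x ")))
  invisible(x)
}

#' Write a cohort to disk (NIfTI volumes + TSV manifest)
#'
#' @param cohort a [simulate_cohort()] object.
#' @param dir output directory (created if needed).
#' @return path of the manifest TSV (columns subject_id, path, label).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(cohort$volumes, function(v) {
    p <- file.path(dir, paste0(v$subject_id, ".nii.gz"))
    write_volume(v, p)
    p
  }, "")
  manifest <- dplyr::mutate(cohort$info, path = paths, .after = "subject_id")
  mpath <- file.path(dir, "cohort.tsv")
  readr::write_tsv(manifest, mpath)
  invisible(mpath)
}

#' Read a cohort from a manifest TSV
#'
#' @param manifest path to a TSV with columns subject_id, path, label
#'   (paths relative to the manifest's directory or absolute).
#' @return a `cnnel_cohort`.
#' @export
read_cohort <- function(manifest) {
  tab <- readr::read_tsv(manifest, show_col_types = FALSE)
  base <- dirname(manifest)
  volumes <- purrr::map2(tab$path, tab$subject_id, function(p, sid) {
    if (!file.exists(p)) p <- file.path(base, p)
    read_volume(p, sid)
  })
  structure(list(volumes = volumes,
                 info = tibble::tibble(subject_id = tab$subject_id,
                                       label = as.integer(tab$label))),
            class = "cnnel_cohort")
}

#' Write an atlas (NIfTI label volume + TSV lookup)
#'
#' @param atlas a `cnnel_atlas`.
#' @param prefix output path prefix; writes `<prefix>.nii.gz` and
#'   `<prefix>.tsv` (columns: label, name, domains semicolon-separated).
#' @return `prefix`, invisibly.
#' @export
write_atlas <- function(atlas, prefix) {
  vol <- as_volume(atlas$label_grid + 0, atlas$affine, "atlas")
  write_volume(vol, paste0(prefix, ".nii.gz"))
  lut <- tibble::tibble(
    label = as.integer(names(atlas$names)),
    name = unname(atlas$names),
    domains = vapply(atlas$domains, paste, "", collapse = ";"))
  readr::write_tsv(lut, paste0(prefix, ".tsv"))
  invisible(prefix)
}

#' Read an atlas written by [write_atlas()]
#'
#' @param prefix path prefix used at write time (or explicit paths via
#'   `nifti` / `lut`).
#' @param nifti,lut optional explicit file paths overriding `prefix`.
#' @return a `cnnel_atlas`.
#' @export
read_atlas <- function(prefix, nifti = paste0(prefix, ".nii.gz"),
                       lut = paste0(prefix, ".tsv")) {
  vol <- read_volume(nifti)
  tab <- readr::read_tsv(lut, show_col_types = FALSE)
  names_vec <- tab$name
  names(names_vec) <- tab$label
  domains <- lapply(strsplit(tab$domains %||% character(), ";"), function(x)
    x[nzchar(x)])
  names(domains) <- tab$label
  structure(list(label_grid = array(as.integer(round(vol$grid)), dim(vol$grid)),
                 affine = vol$affine, names = names_vec, domains = domains),
            class = "cnnel_atlas")
}
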