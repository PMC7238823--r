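# Shared fixtures, built once per test run.

# Separable slice dataset: class 1 brightens a central block.
separable_slices <- function(n = 24, side = 28, shift = 0.3, seed = 1,
                             axis = "sagittal", mm = 0) {
  withr::with_seed(seed, {
    rows <- lapply(seq_len(n), function(i) {
      lab <- i %% 2L
      img <- matrix(runif(side * side, 0, 0.4), side, side)
      if (lab == 1) {
        blk <- seq(round(side * 0.3), round(side * 0.7))
        img[blk, blk] <- img[blk, blk] + shift
      }
      tibble::tibble(axis = axis, mm = mm,
                     subject_id = sprintf("s%02d", i), label = lab,
                     provenance = "original", operation = NA_character_,
                     image = list(pmin(img, 1)))
    })
    dplyr::bind_rows(rows)
  })
}

# Small cached atlas/cohorts so several test files can share them.
fixture_env <- new.env(parent = emptyenv())

tiny_atlas <- function() {
  if (is.null(fixture_env$atlas)) fixture_env$atlas <- make_atlas(c(24, 28, 24), 6, seed = 1)
  fixture_env$atlas
}

# Label of the region whose centroid is nearest the labeled-mask centroid:
# a central, well-sampled region for planting effects.
central_label <- function(atlas) {
  idx <- which(atlas$label_grid > 0)
  co <- arrayInd(idx, dim(atlas$label_grid))
  ctr <- colMeans(co)
  labs <- atlas$label_grid[idx]
  cent <- vapply(sort(unique(labs)), function(l)
    sum((colMeans(co[labs == l, , drop = FALSE]) - ctr)^2), 0)
  sort(unique(labs))[which.min(cent)]
}

tiny_cohort <- function(n = c(8, 8), effect_size = 5, seed = 2,
                        atlas = tiny_atlas(), prefix = NULL) {
  eff <- effect_spec(central_label(atlas), effect_size = effect_size,
                     noise_sd = 0.05)
  co <- simulate_cohort(atlas, eff, n, seed = seed)
  if (!is.null(prefix)) {
    co$info$subject_id <- paste0(prefix, co$info$subject_id)
    for (i in seq_along(co$volumes))
      co$volumes[[i]]$subject_id <- co$info$subject_id[i]
  }
  co
}

# Desk-scale training config: fewer optimizer steps than the full regime,
# compensated by a larger step size.
desk_config <- function(epochs = 6, seed = 1)
  train_config(epochs = epochs, learning_rate = 3e-4, batch_size = 64,
               seed = seed)
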