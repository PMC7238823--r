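# Class-balancing slice augmentation: six mild, label-preserving image
# operations (rotation, translation, gamma correction, additive noise,
# scaling, random affine) with per-class multipliers chosen so that the
# augmented class totals come out (nearly) equal.

#' Per-class augmentation multipliers that balance the classes
#'
#' Given the two original class sizes and the number of new images per
#' original and per operation for the majority class, returns the pair of
#' multipliers `(m_minority, m_majority)` with
#' `m_minority = round(n_majority * m_majority / n_minority)`, so that the
#' augmented class totals differ by less than one original class size.
#'
#' @param n_minority,n_majority original class sizes (>= 1).
#' @param m_majority new images per majority-class original per operation.
#' @return named integer vector `c(m_minority =, m_majority =)`.
#' @export
balance_multipliers <- function(n_minority, n_majority, m_majority) {
  if (n_minority < 1 || n_majority < 1) {
    rlang::abort("both classes must have at least one member")
  }
  m_min <- as.integer(round_half_up(n_majority * m_majority / n_minority))
  c(m_minority = m_min, m_majority = as.integer(m_majority))
}

aug_operations <- function() {
  c("rotation", "translation", "gamma", "noise", "scaling", "affine")
}

#' Augmentation plan
#'
#' @param operations subset of the six operations, in order.
#' @param m_majority new images per majority-class original per operation;
#'   the minority multiplier is derived per dataset by
#'   [balance_multipliers()].
#' @param rotation_deg,translation_mm,gamma_range,noise_sd,scale_range,affine_jitter
#'   operation parameter ranges. Geometric draws are uniform over the range;
#'   `noise_sd` is the additive Gaussian sd on the \[0,1\] intensity scale.
#' @param spacing_mm voxel size used to convert translations to pixels.
#' @param seed integer seed; each generated image uses a substream keyed by
#'   (seed, subject, operation, replicate).
#' @return an object of class `cnnel_augment_plan`.
#' @export
augment_plan <- function(operations = aug_operations(), m_majority = 10,
                         rotation_deg = 10, translation_mm = 6,
                         gamma_range = c(0.7, 1.4), noise_sd = 0.02,
                         scale_range = c(0.92, 1.08), affine_jitter = 0.06,
                         spacing_mm = 1.5, seed = 1) {
  operations <- match.arg(operations, aug_operations(), several.ok = TRUE)
  assert_that(m_majority >= 0 && m_majority == round(m_majority),
              "m_majority must be a non-negative integer")
  structure(list(operations = operations, m_majority = as.integer(m_majority),
                 rotation_deg = rotation_deg, translation_mm = translation_mm,
                 gamma_range = gamma_range, noise_sd = noise_sd,
                 scale_range = scale_range, affine_jitter = affine_jitter,
                 spacing_mm = spacing_mm, seed = as.integer(seed)),
            class = "cnnel_augment_plan")
}

# Bilinear resampling of `img` under the output->input pixel map
# p_in = A %*% (p_out - center) + center + shift, with edge clamping.
warp_bilinear <- function(img, A, shift = c(0, 0)) {
  d <- dim(img)
  ctr <- (d + 1) / 2
  rr <- seq_len(d[1]); cc <- seq_len(d[2])
  # source coordinates for every output pixel
  sr <- A[1, 1] * (rr - ctr[1]) + ctr[1] + shift[1]
  sr <- outer(sr, A[1, 2] * (cc - ctr[2]), `+`)
  sc <- outer(A[2, 1] * (rr - ctr[1]), A[2, 2] * (cc - ctr[2]) + ctr[2] + shift[2], `+`)
  sr <- pmin(pmax(sr, 1), d[1])
  sc <- pmin(pmax(sc, 1), d[2])
  r0 <- pmin(floor(sr), d[1] - 1); c0 <- pmin(floor(sc), d[2] - 1)
  fr <- sr - r0; fc <- sc - c0
  i00 <- cbind(as.vector(r0), as.vector(c0))
  v00 <- img[i00]
  v10 <- img[i00 + rep(c(1L, 0L), each = nrow(i00))]
  v01 <- img[i00 + rep(c(0L, 1L), each = nrow(i00))]
  v11 <- img[i00 + 1L]
  fr <- as.vector(fr); fc <- as.vector(fc)
  out <- (1 - fr) * (1 - fc) * v00 + fr * (1 - fc) * v10 +
    (1 - fr) * fc * v01 + fr * fc * v11
  matrix(out, d[1], d[2])
}

#' Apply one augmentation operation to a slice
#'
#' Output has the same shape as the input and values clipped to \[0, 1\];
#' deterministic given `seed`. Geometric operations use bilinear
#' interpolation with edge padding. A gamma exponent of 1, a rotation of 0
#' degrees or a translation of 0 return the input unchanged.
#'
#' @param image square 2D matrix with values in \[0, 1\].
#' @param op_name one of `rotation`, `translation`, `gamma`, `noise`,
#'   `scaling`, `affine`.
#' @param plan a [augment_plan()] holding the parameter ranges.
#' @param seed integer seed for the operation's random draw.
#' @return a matrix of the same shape.
#' @export
apply_operation <- function(image, op_name, plan = augment_plan(), seed = 1) {
  assert_that(is.matrix(image) && nrow(image) == ncol(image),
              "image must be a square matrix")
  if (!op_name %in% aug_operations()) {
    rlang::abort(sprintf("unknown augmentation operation '%s'", op_name))
  }
  out <- with_seed(seed, switch(
    op_name,
    rotation = {
      th <- runif(1, -plan$rotation_deg, plan$rotation_deg) * pi / 180
      if (th == 0) image else
        warp_bilinear(image, matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2))
    },
    translation = {
      px <- plan$translation_mm / plan$spacing_mm
      sh <- runif(2, -px, px)
      if (all(sh == 0)) image else warp_bilinear(image, diag(2), shift = sh)
    },
    gamma = {
      g <- runif(1, plan$gamma_range[1], plan$gamma_range[2])
      clip01(image)^g
    },
    noise = image + rnorm(length(image), sd = plan$noise_sd),
    scaling = {
      s <- runif(1, plan$scale_range[1], plan$scale_range[2])
      warp_bilinear(image, diag(2) / s)
    },
    affine = {
      J <- matrix(runif(4, -plan$affine_jitter, plan$affine_jitter), 2)
      warp_bilinear(image, solve(diag(2) + J))
    }))
  clip01(out)
}

#' Expand a slice dataset with balanced augmentation
#'
#' For each (axis, coordinate) dataset, appends `n_class * m_class` new
#' images per operation, where the per-class multipliers come from
#' [balance_multipliers()] applied to that dataset's class counts (equal
#' classes use `m_majority` for both). Augmented rows carry provenance
#' `"augmented"`, the operation name and the source subject id, and must
#' never cross into validation or test partitions.
#'
#' @param slices a [build_slice_dataset()] tibble.
#' @param plan an [augment_plan()].
#' @return the augmented `cnnel_slices` tibble (originals first).
#' @export
build_augmented_dataset <- function(slices, plan) {
  stopifnot(inherits(plan, "cnnel_augment_plan"))
  if (length(plan$operations) == 0 || plan$m_majority == 0) return(slices)
  assert_that(all(slices$provenance == "original"),
              "augmentation input must contain only original slices")
  groups <- dplyr::group_split(dplyr::group_by(slices, .data$axis, .data$mm))
  aug <- purrr::map(groups, function(g) {
    n0 <- sum(g$label == 0); n1 <- sum(g$label == 1)
    assert_that(n0 > 0 && n1 > 0, "each slice dataset needs both classes")
    if (n0 == n1) {
      m <- c(`0` = plan$m_majority, `1` = plan$m_majority)
    } else {
      minority <- if (n0 < n1) 0L else 1L
      bm <- balance_multipliers(min(n0, n1), max(n0, n1), plan$m_majority)
      m <- c(bm[["m_majority"]], bm[["m_majority"]])
      names(m) <- c("0", "1")
      m[as.character(minority)] <- bm[["m_minority"]]
    }
    new_rows <- purrr::pmap(g, function(axis, mm, subject_id, label,
                                        provenance, operation, image) {
      mk <- m[[as.character(label)]]
      if (mk == 0) return(NULL)
      combos <- expand.grid(rep = seq_len(mk), op = plan$operations,
                            stringsAsFactors = FALSE)
      imgs <- purrr::map2(combos$op, combos$rep, function(op, rep) {
        apply_operation(image, op, plan,
                        seed = derive_seed(plan$seed, axis_dim(as.character(axis)),
                                           round(mm * 100),
                                           which(aug_operations() == op), rep,
                                           strtoi(substr(digest_id(subject_id), 1, 7), 16L)))
      })
      tibble::tibble(axis = as.character(axis), mm = mm,
                     subject_id = subject_id, label = label,
                     provenance = "augmented", operation = combos$op,
                     image = imgs)
    })
    dplyr::bind_rows(new_rows)
  })
  out <- dplyr::bind_rows(c(list(tibble::as_tibble(slices)), aug))
  out$axis <- factor(as.character(out$axis), levels = axis_levels())
  structure(out, side = attr(slices, "side"),
            class = c("cnnel_slices", class(tibble::tibble())))
}

# Small stable string hash (hex) so subject ids key RNG substreams.
digest_id <- function(x) {
  b <- utf8ToInt(x)
  h <- 5381
  for (v in b) h <- (h * 33 + v) %% 4294967291
  sprintf("%08x", h)
}
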