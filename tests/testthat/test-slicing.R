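test_that("intensity normalization rescales by the volume maximum", {
  g <- array(0, c(5, 5, 5)); g[2, 3, 4] <- 1000; g[1, 1, 1] <- 250
  v <- normalize_intensity(as_volume(g))
  expect_equal(v$grid[1, 1, 1], 0.25)
  expect_equal(max(v$grid), 1)
  expect_true(all(v$grid >= 0 & v$grid <= 1))
  # constant positive volume -> all ones; idempotence
  const <- normalize_intensity(as_volume(array(7, c(3, 3, 3))))
  expect_true(all(const$grid == 1))
  expect_identical(normalize_intensity(v)$grid, v$grid)
  expect_error(normalize_intensity(as_volume(array(0, c(2, 2, 2)))),
               "degenerate")
})

test_that("the full-scale plan enumerates 40 + 50 + 33 = 123 slice positions", {
  p <- slice_plan(c(121, 145, 121))
  n <- table(p$coords$axis)
  expect_equal(unname(n[["sagittal"]]), 40)
  expect_equal(unname(n[["coronal"]]), 50)
  expect_equal(unname(n[["transverse"]]), 33)
  expect_equal(nrow(p$coords), 123)
  expect_equal(p$side, 145)
})

test_that("slice coordinates form arithmetic sequences mapping to every-2nd voxel index", {
  for (shape in list(c(121, 145, 121), c(24, 28, 24))) {
    p <- slice_plan(shape)
    aff <- mni_affine(shape)
    for (ax in c("sagittal", "coronal", "transverse")) {
      mm <- select_slice_coordinates(p, ax)
      a <- match(ax, c("sagittal", "coronal", "transverse"))
      expect_true(all(diff(mm) > 0))
      expect_equal(diff(mm), rep(2 * aff[a, a], length(mm) - 1))
      idx <- (mm - aff[a, 4]) / aff[a, a]
      expect_equal(idx, round(idx))
      expect_true(all(idx >= 0 & idx <= shape[a] - 1))
      expect_equal(unique(diff(idx)), 2)
    }
  }
})

test_that("mm crop windows are honoured and validated", {
  shape <- c(24, 28, 24)
  aff <- mni_affine(shape)
  mid <- aff[1, 1] * 10 + aff[1, 4]  # exact grid coordinate on X
  p <- slice_plan(shape, crop = list(sagittal = c(mid, mid),
                                     coronal = c(-10, 10),
                                     transverse = c(-10, 10)))
  expect_length(select_slice_coordinates(p, "sagittal"), 1)
  expect_equal(select_slice_coordinates(p, "sagittal"), mid)
  expect_error(slice_plan(shape, crop = list(sagittal = c(-500, 500),
                                             coronal = c(-10, 10),
                                             transverse = c(-10, 10))),
               "outside")
})

test_that("extract_slice matches direct array indexing on all three axes", {
  shape <- c(11, 13, 9)
  g <- array(seq_len(prod(shape)) / prod(shape), shape)
  v <- as_volume(g)
  aff <- v$affine
  # sagittal slice sizes on the full grid are 145 x 121 etc.
  expect_identical(dim(extract_slice(v, "sagittal", aff[1, 4])), c(13L, 9L))
  expect_identical(dim(extract_slice(v, "coronal", aff[2, 4])), c(11L, 9L))
  expect_identical(dim(extract_slice(v, "transverse", aff[3, 4])), c(11L, 13L))
  for (i in c(0, 3, shape[1] - 1)) {
    mm <- aff[1, 1] * i + aff[1, 4]
    expect_identical(extract_slice(v, "sagittal", mm), g[i + 1, , ])
  }
  expect_identical(extract_slice(v, "coronal", aff[2, 2] * 5 + aff[2, 4]),
                   g[, 6, ])
  expect_identical(extract_slice(v, "transverse", aff[3, 3] * 2 + aff[3, 4]),
                   g[, , 3])
  # constant along X -> all sagittal slices identical
  gc <- array(rep(g[1, , ], each = shape[1]), shape)
  vc <- as_volume(gc)
  s1 <- extract_slice(vc, "sagittal", aff[1, 4])
  s2 <- extract_slice(vc, "sagittal", aff[1, 1] * 7 + aff[1, 4])
  expect_identical(s1, s2)
  # off-grid coordinate errors and names the nearest grid coordinate
  err <- tryCatch(extract_slice(v, "sagittal", aff[1, 4] + 0.6 * aff[1, 1]),
                  error = conditionMessage)
  expect_match(err, "nearest grid coordinate")
  expect_match(err, sprintf("%.6g", aff[1, 1] * 1 + aff[1, 4]), fixed = TRUE)
})

test_that("full-scale slices have the stated in-plane sizes", {
  g <- array(0, c(121, 145, 121))
  v <- as_volume(g)
  aff <- v$affine
  expect_identical(dim(extract_slice(v, "sagittal", aff[1, 4])), c(145L, 121L))
  expect_identical(dim(extract_slice(v, "coronal", aff[2, 4])), c(121L, 121L))
  expect_identical(dim(extract_slice(v, "transverse", aff[3, 4])), c(121L, 145L))
})

test_that("pad_to_square centers content, replicates near edges, zero-fills beyond", {
  img <- matrix(runif(145 * 121, 0.1, 1), 145, 121)
  out <- pad_to_square(img, 145)
  expect_identical(dim(out), c(145L, 145L))
  expect_identical(out[, 13:133], img)          # (145-121)/2 = 12 each side
  img2 <- matrix(runif(121 * 121, 0.1, 1), 121, 121)
  out2 <- pad_to_square(img2, 145)
  expect_identical(out2[13:133, 13:133], img2)
  # 4-voxel replicate band then zeros
  expect_identical(out2[9:12, 13:133], matrix(rep(img2[1, ], each = 4), 4))
  expect_true(all(out2[1:8, ] == 0))
  expect_true(all(out2[, 1:8] == 0))
  # identity and error cases
  expect_identical(pad_to_square(img2, 121), img2)
  expect_error(pad_to_square(out, 121), "larger")
  # odd deficit: extra padding goes to the high-index side
  odd <- matrix(1, 4, 5)
  po <- pad_to_square(odd, 7, edge_margin = 0)
  expect_identical(which(po[, 3] == 1), 2:5)    # rows: pad 1 low, 2 high
  expect_identical(which(po[4, ] == 1), 2:6)    # cols: pad 1 low, 1 high
})

test_that("build_slice_dataset wires plan, normalization and padding together", {
  co <- tiny_cohort(c(2, 2))
  p <- slice_plan(c(24, 28, 24))
  ds <- build_slice_dataset(co, p)
  expect_s3_class(ds, "cnnel_slices")
  expect_equal(nrow(ds), nrow(p$coords) * 4)
  expect_true(all(vapply(ds$image, function(m) all(dim(m) == p$side), TRUE)))
  expect_true(all(ds$provenance == "original"))
  # one row per subject per planned slice
  per <- table(ds$axis, ds$mm)[table(ds$axis, ds$mm) > 0]
  expect_true(all(per == 4))
  # padded sub-grid equals the normalized extracted plane (round-trip)
  v <- normalize_intensity(co$volumes[[1]])
  mm <- select_slice_coordinates(p, "coronal")[2]
  raw <- extract_slice(v, "coronal", mm)
  row <- ds[ds$axis == "coronal" & abs(ds$mm - mm) < 1e-9 &
              ds$subject_id == v$subject_id, ]
  expect_identical(row$image[[1]], pad_to_square(raw, p$side))
})
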