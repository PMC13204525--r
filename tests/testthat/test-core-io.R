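test_that("NIfTI round trip preserves grid and spacing", {
  dir <- withr::local_tempdir()
  v <- pet_volume(array(0, c(4, 4, 4)), spacing = c(1.5, 2, 0.75))
  path <- file.path(dir, "v.nii.gz")
  write_volume(v, path)
  r <- read_volume(path)
  expect_equal(r$data, v$data)
  expect_equal(r$spacing, v$spacing, tolerance = 1e-6)

  set.seed(2)
  v2 <- pet_volume(array(rnorm(64), c(4, 4, 4)))
  write_volume(v2, path)
  expect_equal(read_volume(path)$data, v2$data, tolerance = 1e-6)
})

test_that("masks binarize at > 0 on read and construction", {
  dir <- withr::local_tempdir()
  m <- array(0L, c(3, 3, 3)); m[2, 2, 2] <- 255L; m[1, 1, 1] <- 7L
  path <- file.path(dir, "m.nii.gz")
  write_volume(pet_volume(m), path)
  rm_ <- read_mask(path)
  expect_setequal(unique(as.vector(rm_$data)), c(0L, 1L))
  expect_equal(sum(rm_$data), 2L)
  expect_error(read_volume(file.path(dir, "nope.nii")), "not found")
})

test_that("volume/mask shape mismatch raises a geometry error", {
  v <- pet_volume(array(0, c(8, 8, 8)))
  m <- roi_mask(array(1L, c(9, 9, 9)))
  expect_error(crop_with_margin(v, m), "geometry")
  expect_error(resample_to_shape(v, m), "geometry")
})

test_that("crop_with_margin covers the dilated bounding box, clipped", {
  # single center voxel, margin 5 fills an 11-cube exactly
  v <- pet_volume(array(seq_len(11^3) / 11^3, c(11, 11, 11)))
  m <- array(0L, c(11, 11, 11)); m[6, 6, 6] <- 1L
  cr <- crop_with_margin(v, roi_mask(m), margin = 5L)
  expect_equal(dim(cr$volume$data), c(11L, 11L, 11L))
  expect_equal(sum(cr$mask$data), 1L)

  # corner voxel: clipping leaves a 6-cube
  m2 <- array(0L, c(11, 11, 11)); m2[1, 1, 1] <- 1L
  cr2 <- crop_with_margin(v, roi_mask(m2), margin = 5L)
  expect_equal(dim(cr2$volume$data), c(6L, 6L, 6L))
  expect_equal(unname(cr2$bbox["start", ]), c(0L, 0L, 0L))
  expect_equal(unname(cr2$bbox["end", ]), c(6L, 6L, 6L))

  # margin 0 equals the tight bounding box; foreground count unchanged
  tc <- toy_case(3)
  cr3 <- crop_with_margin(tc$volume, tc$mask, margin = 0L)
  idx <- which(tc$mask$data > 0, arr.ind = TRUE)
  expect_equal(dim(cr3$mask$data), unname(apply(idx, 2, max) - apply(idx, 2, min) + 1L))
  expect_equal(sum(cr3$mask$data), sum(tc$mask$data))
  expect_error(crop_with_margin(v, roi_mask(array(0L, c(11, 11, 11)))), "empty")
})

test_that("resample preserves constants, binarity, and edge locations", {
  v <- pet_volume(array(7, c(16, 16, 16)))
  m <- ball_mask(c(16L, 16L, 16L), 5)
  rs <- resample_to_shape(v, m, c(64, 64, 64))
  expect_equal(dim(rs$volume$data), c(64L, 64L, 64L))
  expect_true(all(abs(rs$volume$data - 7) < 1e-12))
  expect_setequal(unique(as.vector(rs$mask$data)), c(0L, 1L))

  # axis-aligned step edge, upscaled 2x: brute-force index mapping says the
  # output edge must sit within one voxel of twice the input edge position
  n <- 8L
  step <- array(0, c(n, n, n)); step[5:n, , ] <- 1
  rs2 <- resample_to_shape(pet_volume(step), roi_mask(array(1L, c(n, n, n))),
                           c(2L * n, 2L * n, 2L * n))
  profile <- rs2$volume$data[, 8, 8]
  edge_out <- min(which(profile > 0.5))
  expect_lte(abs(edge_out - 2 * 5), 2) # within 1 voxel of the scaled edge
  expect_error(resample_to_shape(pet_volume(array(0, c(1, 4, 4))),
                                 roi_mask(array(1L, c(1, 4, 4)))),
               "degenerate")
})

test_that("crop and resample are deterministic", {
  tc <- toy_case(5)
  a <- resample_to_shape(tc$volume, tc$mask, c(32, 32, 32))
  b <- resample_to_shape(tc$volume, tc$mask, c(32, 32, 32))
  expect_identical(a$volume$data, b$volume$data)
  c1 <- crop_with_margin(tc$volume, tc$mask, 5L)
  c2 <- crop_with_margin(tc$volume, tc$mask, 5L)
  expect_identical(c1$bbox, c2$bbox)
})

test_that("derived per-stage seeds are deterministic and distinct", {
  expect_identical(derive_seed(42L, "deep"), derive_seed(42L, "deep"))
  expect_false(derive_seed(42L, "deep") == derive_seed(42L, "habitat"))
  expect_true(derive_seed(.Machine$integer.max, "x") < 2^31)
})
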