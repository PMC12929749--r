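test_that("volume in mm^3 is count times voxel volume", {
  m <- array(0L, c(4, 8, 8)); m[1, 1:5, 1] <- 1L; m[2, 1:5, 2] <- 1L
  est <- mask_volume_mm3(binary_mask(m, c(4.8, 0.5, 0.5)))
  expect_identical(est$voxel_count, 10L)
  expect_equal(est$mm3, 12)

  empty <- mask_volume_mm3(tiny_mask(c(3, 3, 3)))
  expect_identical(empty$voxel_count, 0L)
  expect_identical(empty$mm3, 0)

  full <- binary_mask(array(1L, c(4, 4, 2)), c(1, 1, 1))
  expect_equal(mask_volume_mm3(full)$mm3, 32)
})

test_that("mask volume is additive over disjoint masks", {
  set.seed(11)
  for (i in 1:20) {
    d <- c(sample(2:6, 1), sample(4:10, 1), sample(4:10, 1))
    a <- random_mask(d, 0.3, spacing = c(4.8, 0.5, 0.5))
    b <- random_mask(d, 0.3, spacing = c(4.8, 0.5, 0.5))
    b$data[a$data == 1L] <- 0L  # enforce disjointness
    u <- binary_mask(a$data + b$data, a$spacing)
    expect_equal(mask_volume_mm3(u)$mm3,
                 mask_volume_mm3(a)$mm3 + mask_volume_mm3(b)$mm3)
  }
})

test_that("Dice matches the overlap formula and its boundary cases", {
  a <- tiny_mask(c(2, 4, 4), cbind(1, 1:2, 1:2))
  expect_equal(dice_coefficient(a, a), 1)

  x <- tiny_mask(c(2, 4, 4)); x$data[1, 1:2, 1:2] <- 1L  # |X| = 4
  y <- tiny_mask(c(2, 4, 4)); y$data[1, 1:3, 1:2] <- 1L  # |Y| = 6, overlap 3
  x$data[1, 2, 2] <- 0L; x$data[2, 4, 4] <- 1L           # overlap 3, |X| = 4
  expect_equal(dice_coefficient(x, y), 2 * 3 / (4 + 6))

  disj <- tiny_mask(c(2, 4, 4), cbind(2, 1, 1))
  expect_equal(dice_coefficient(disj, y), 0)
  empty_pred <- tiny_mask(c(2, 4, 4))
  expect_equal(dice_coefficient(empty_pred, y), 0)
  expect_error(dice_coefficient(y, tiny_mask(c(2, 4, 4))), "positive")
  expect_error(dice_coefficient(y, tiny_mask(c(3, 4, 4), cbind(1, 1, 1))),
               "geometry")
})

test_that("Dice is symmetric and permutation invariant", {
  set.seed(12)
  for (i in 1:10) {
    d <- c(3, 5, 5)
    a <- random_mask(d, 0.4); b <- random_mask(d, 0.4)
    if (sum(a$data) == 0) a$data[1, 1, 1] <- 1L
    if (sum(b$data) == 0) b$data[1, 1, 1] <- 1L
    expect_equal(dice_coefficient(a, b), dice_coefficient(b, a))
    perm <- sample(prod(d))
    ap <- binary_mask(array(a$data[perm], d), a$spacing)
    bp <- binary_mask(array(b$data[perm], d), b$spacing)
    expect_equal(dice_coefficient(ap, bp), dice_coefficient(a, b))
  }
})

test_that("constructors enforce the data-model invariants", {
  expect_error(image_volume(matrix(1, 2, 2), c(1, 1, 1)), "3D")
  expect_error(image_volume(array(NA_real_, c(2, 2, 2)), c(1, 1, 1)), "finite")
  expect_error(image_volume(array(1, c(2, 2, 2)), c(0, 1, 1)), "positive")
  expect_error(binary_mask(array(2L, c(2, 2, 2)), c(1, 1, 1)), "0 or 1")
})

test_that("NIfTI round trip preserves grid and anisotropic spacing", {
  set.seed(13)
  vol <- random_volume(c(8, 16, 16), spacing = c(4.8, 0.5, 0.5))
  f <- tempfile(fileext = ".nii.gz")
  write_volume(vol, f)
  back <- read_volume(f)
  expect_equal(back$data, vol$data)
  expect_equal(back$spacing, vol$spacing, tolerance = 1e-6)

  msk <- random_mask(c(6, 12, 12), 0.3, spacing = c(5.2, 0.4, 0.4))
  fm <- tempfile(fileext = ".nii.gz")
  write_mask(msk, fm)
  backm <- read_mask(fm)
  expect_identical(backm$data, msk$data)
  expect_equal(backm$spacing, msk$spacing, tolerance = 1e-6)
})

test_that("non-binary NIfTI content is rejected as a mask", {
  bad <- image_volume(array(2, c(4, 8, 8)), c(1, 1, 1))
  f <- tempfile(fileext = ".nii.gz")
  write_volume(bad, f)
  expect_error(read_mask(f), "0 or 1")
})
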