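test_that("axial stretching hits the target length and records the factor", {
  v32 <- random_volume(c(32, 64, 64))
  s <- stretch_axial(v32)
  expect_identical(dim(s$object$data)[1], 64L)
  expect_equal(s$factor, 2)

  v70 <- random_volume(c(70, 64, 64))
  s70 <- stretch_axial(v70)
  expect_identical(s70$object$data, v70$data)
  expect_equal(s70$factor, 1)
})

test_that("mask stretch plus inverse mapping recovers the mask exactly", {
  set.seed(71)
  for (nz in c(32, 26, 41, 60)) {
    m <- random_mask(c(nz, 16, 16), 0.3)
    s <- stretch_axial(m)
    back <- rpeseg:::unstretch_z_data(s$object$data, nz)
    expect_identical(back, m$data)
    expect_true(all(s$object$data %in% c(0L, 1L)))
  }
})

test_that("the tile lattice strides by 32 and clamps the final offset", {
  expect_identical(tile_lattice(128), c(1L, 33L, 65L))
  expect_identical(tile_lattice(64), 1L)
  expect_identical(tile_lattice(100), c(1L, 33L, 37L))
  expect_error(tile_lattice(40), "geometry")
})

test_that("tile selection follows the one-third / absolute-count rule", {
  # all 30 region pixels inside a single square: kept by the 1/3 rule
  slice <- matrix(0, 128, 128)
  cross <- matrix(0L, 128, 128); cross[10:14, 10:15] <- 1L
  tiles <- sample_tiles(slice, cross, "axial", 1, abs_min = 1000)
  expect_identical(tile_manifest(tiles)$row, 1L)
  expect_identical(tile_manifest(tiles)$col, 1L)

  # an empty cross-section yields no tiles, and zero-overlap squares never pass
  expect_length(sample_tiles(slice, matrix(0L, 128, 128), "axial", 1), 0L)
  spread <- matrix(0L, 128, 128); spread[100:110, 100:110] <- 1L
  kept <- tile_manifest(sample_tiles(slice, spread, "axial", 1, abs_min = 1000))
  expect_true(all(kept$row + 63 >= 100 & kept$col + 63 >= 100))
})

test_that("tile selection equals brute-force rule evaluation on random inputs", {
  set.seed(72)
  for (i in 1:100) {
    n <- sample(c(96, 128, 160), 1)
    cross <- matrix(0L, n, n)
    k <- sample(1:3, 1)
    for (j in 1:k) {
      r <- sample(n - 10, 1); c <- sample(n - 10, 1)
      cross[r:(r + sample(3:10, 1)), c:(c + sample(3:10, 1))] <- 1L
    }
    cross <- cross[1:n, 1:n]
    abs_min <- sample(c(30, 62.5, 1000), 1)
    slice <- matrix(runif(n * n), n, n)
    kept <- tile_manifest(sample_tiles(slice, cross, "axial", 1,
                                       abs_min = abs_min))
    total <- sum(cross)
    brute <- tibble::tibble(row = integer(0), col = integer(0))
    for (r0 in tile_lattice(n)) for (c0 in tile_lattice(n)) {
      cnt <- sum(cross[r0:(r0 + 63), c0:(c0 + 63)])
      if (cnt >= total / 3 || cnt >= abs_min)
        brute <- dplyr::bind_rows(brute, tibble::tibble(row = r0, col = c0))
    }
    expect_identical(kept[, c("row", "col")], brute)
  }
})

test_that("reassembly averages overlaps, zero-fills gaps, ignores order", {
  dim3 <- c(70, 128, 128)
  t1 <- list(pixels = NULL, view = "axial", index = 3L, row = 1L, col = 1L,
             stretch = 1)
  t2 <- list(pixels = NULL, view = "axial", index = 3L, row = 1L, col = 33L,
             stretch = 1)
  p1 <- matrix(1, 64, 64); p0 <- matrix(0, 64, 64)

  one <- reassemble(list(t1), list(p1), dim3)
  expect_true(all(one[3, 1:64, 1:64] == 1))
  expect_identical(sum(one), 64 * 64)

  two <- reassemble(list(t1, t2), list(p1, p0), dim3)
  expect_true(all(two[3, 1:64, 33:64] == 0.5))
  expect_true(all(two[3, 1:64, 1:32] == 1))
  expect_true(all(two[3, 1:64, 97:128] == 0))

  swapped <- reassemble(list(t2, t1), list(p0, p1), dim3)
  expect_identical(two, swapped)

  none <- reassemble(list(), list(), c(4, 64, 64))
  expect_true(all(none == 0))
})

test_that("reassembly undoes the axial stretch for coronal tiles", {
  nz <- 32L
  t1 <- list(pixels = NULL, view = "coronal", index = 5L, row = 1L, col = 1L,
             stretch = 2)
  out <- reassemble(list(t1), list(matrix(1, 64, 64)), c(nz, 80, 80))
  expect_identical(dim(out), c(32L, 80L, 80L))
  expect_true(all(out[1:32, 5, 1:64] == 1))
  expect_true(all(out[, -5, ] == 0))
})
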