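test_that("U-Net builds are seeded and mask-shaped", {
  a <- build_unet(seed = 4)
  b <- build_unet(seed = 4)
  x <- list(matrix(runif(64 * 64), 64, 64))
  expect_identical(predict_tiles(a, x), predict_tiles(b, x))
  p <- predict_tiles(a, x)[[1]]
  expect_identical(dim(p), c(64L, 64L))
  expect_true(all(p > 0 & p < 1))
})

test_that("U-Net training needs lesion pixels and reduces the Dice loss", {
  set.seed(81)
  tx <- lapply(1:16, function(i) {
    m <- matrix(runif(64 * 64, 0, 0.3), 64, 64)
    m[20:35, 25:40] <- runif(16 * 16, 0.8, 1)
    m
  })
  ty <- lapply(1:16, function(i) {
    m <- matrix(0, 64, 64); m[20:35, 25:40] <- 1; m
  })
  un <- build_unet(seed = 2)
  expect_error(train_unet(un, tx, lapply(ty, function(m) m * 0)),
               "empty")
  fit <- train_unet(un, tx, ty, seg_train_config(seed = 3))  # full 30 epochs
  expect_length(fit$history, 30L)
  expect_lt(fit$history[30], fit$history[1])
  # an easy saturated task ends near the loss floor
  expect_lt(fit$history[30], 0.2)
})

test_that("majority vote equals the per-voxel truth table", {
  d <- c(4, 4, 4)
  set.seed(82)
  for (i in 1:20) {
    m1 <- random_mask(d, 0.5); m2 <- random_mask(d, 0.5); m3 <- random_mask(d, 0.5)
    vote <- majority_vote(m1, m2, m3)
    brute <- array(0L, d)
    for (j in seq_len(prod(d)))
      brute[j] <- as.integer(m1$data[j] + m2$data[j] + m3$data[j] >= 2L)
    expect_identical(vote$data, brute)
    # bounded between intersection and union
    expect_true(all(vote$data >= (m1$data & m2$data & m3$data)))
    expect_true(all(vote$data <= (m1$data | m2$data | m3$data)))
    # two agreeing masks dominate
    expect_identical(majority_vote(m1, m1, m3)$data, m1$data)
  }
  expect_identical(majority_vote(m1, m2, m3)$data,
                   majority_vote(m2, m3, m1)$data)
})

test_that("predict_view_mask respects the region and the zero-init rule", {
  cs <- easy_phantom(83)
  un <- build_unet(seed = 5, view = "axial")
  empty_region <- build_region(rep(0, dim(cs$volume$data)[1]),
                               rep(0, dim(cs$volume$data)[2]),
                               rep(0, dim(cs$volume$data)[3]))
  out <- predict_view_mask(un, cs$volume, empty_region, "axial", abs_min = 15)
  expect_identical(sum(out$data), 0L)
  expect_identical(attr(out, "n_tiles"), 0L)

  reg <- build_region(slice_labels(cs$mask, "axial"),
                      slice_labels(cs$mask, "coronal"),
                      slice_labels(cs$mask, "sagittal"))
  pred <- predict_view_mask(un, cs$volume, reg, "axial", threshold = 0.01,
                            abs_min = 15)
  # with a near-zero threshold the mask fills exactly the tile footprints:
  # every positive voxel must lie on an axial slice inside the region
  pos <- which(pred$data == 1L, arr.ind = TRUE)
  expect_true(all(pos[, 1] %in% reg$z))
})
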