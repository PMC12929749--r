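test_that("generation is bit-reproducible from the seed", {
  a <- generate_phantom(phantom_spec(in_plane = 64, seed = 101))
  b <- generate_phantom(phantom_spec(in_plane = 64, seed = 101))
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$mask$data, b$mask$data)
  c2 <- generate_phantom(phantom_spec(in_plane = 64, seed = 102))
  expect_false(identical(a$mask$data, c2$mask$data))
})

test_that("zero target volume yields a lesion-free phantom", {
  neg <- generate_phantom(phantom_spec(in_plane = 64, lesion_volume_mm3 = 0,
                                       seed = 3))
  expect_identical(sum(neg$mask$data), 0L)
})

test_that("an infeasible lesion volume is rejected", {
  expect_error(generate_phantom(phantom_spec(in_plane = 64,
                                             lesion_volume_mm3 = 0.01,
                                             seed = 1)),
               "smaller than one voxel")
  expect_error(generate_phantom(phantom_spec(in_plane = 64,
                                             lesion_volume_mm3 = 1e7,
                                             seed = 1)),
               "infeasible")
})

test_that("sparsity, connectivity and volume recovery hold across seeds", {
  fracs <- numeric(0); ratios <- numeric(0)
  for (s in 1:100) {
    cs <- generate_phantom(phantom_spec(seed = 1000 + s))
    fracs <- c(fracs, 100 * mean(cs$mask$data))
    ratios <- c(ratios, cs$lesion_mm3 / cs$target_mm3)
    lab <- rpeseg:::cpp_label_components(cs$mask$data, dim(cs$mask$data))
    expect_identical(max(lab), 1L)  # exactly one 26-connected component
  }
  expect_gte(sum(fracs >= 0.0023 & fracs <= 0.31), 95)
  expect_true(all(abs(ratios - 1) <= 0.25))
})

test_that("cohorts are reproducible, distinct and singleton-consistent", {
  co1 <- generate_cohort(5, phantom_spec(in_plane = 64), seed = 7)
  co2 <- generate_cohort(5, phantom_spec(in_plane = 64), seed = 7)
  expect_identical(lapply(co1, function(x) x$mask$data),
                   lapply(co2, function(x) x$mask$data))
  geoms <- vapply(co1, function(x) paste(dim(x$volume$data), collapse = "x"),
                  character(1))
  expect_gt(length(unique(geoms)), 1L)

  other <- generate_cohort(5, phantom_spec(in_plane = 64), seed = 8)
  expect_false(identical(co1[[1]]$mask$data, other[[1]]$mask$data))

  single <- generate_cohort(1, phantom_spec(in_plane = 64), seed = 7)
  sub <- withr::with_seed(7L, sample.int(.Machine$integer.max - 1L, 1))
  direct <- generate_phantom(phantom_spec(in_plane = 64, seed = sub))
  expect_identical(single[[1]]$mask$data, direct$mask$data)
})

test_that("lesion intensity is separable inside its bounding box", {
  # the tile segmenter can only work if a plain intensity threshold already
  # separates lesion from local background reasonably well
  for (s in c(5, 21, 33)) {
    cs <- generate_phantom(phantom_spec(seed = s))
    zr <- range(which(apply(cs$mask$data, 1, max) > 0))
    yr <- range(which(apply(cs$mask$data, 2, max) > 0))
    xr <- range(which(apply(cs$mask$data, 3, max) > 0))
    sub <- cs$volume$data[zr[1]:zr[2], yr[1]:yr[2], xr[1]:xr[2]]
    msub <- cs$mask$data[zr[1]:zr[2], yr[1]:yr[2], xr[1]:xr[2]]
    best <- max(vapply(quantile(sub, seq(0.3, 0.95, 0.05)), function(t) {
      p <- sub >= t
      2 * sum(p & msub == 1) / (sum(p) + sum(msub))
    }, numeric(1)))
    expect_gt(best, 0.7)
  }
})

test_that("a cohort writes paired NIfTI files and a manifest", {
  dir <- tempfile("cohort")
  co <- generate_cohort(2, phantom_spec(in_plane = 64), seed = 9)
  manifest <- write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(all(file.exists(file.path(dir, paste0(manifest$id, "_img.nii.gz")))))
  back <- read_mask(file.path(dir, paste0(manifest$id[1], "_mask.nii.gz")))
  expect_identical(back$data, co[[1]]$mask$data)
  expect_equal(manifest$lesion_mm3[1], co[[1]]$lesion_mm3)
})
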