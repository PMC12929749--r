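# The compiled engine is validated against a plain-R double-precision
# reference implementation (helper-reference.R): forward passes must agree to
# float tolerance, and analytic parameter gradients must match central finite
# differences of the reference loss.

test_that("compiled forward passes agree with the plain-R reference", {
  set.seed(51)
  clf <- build_classifier(seed = 5)
  xs <- lapply(1:2, function(i) matrix(runif(128 * 128), 128, 128))
  p_cpp <- predict_slices(clf, xs)
  p_ref <- vapply(xs, function(x) ref_encoder_forward(clf$weights, x),
                  numeric(1))
  expect_equal(p_cpp, p_ref, tolerance = 1e-5)

  un <- build_unet(seed = 6)
  tx <- lapply(1:2, function(i) matrix(runif(64 * 64), 64, 64))
  q_cpp <- predict_tiles(un, tx)
  q_ref <- lapply(tx, function(x) matrix(ref_unet_forward(un$weights, x), 64, 64))
  expect_equal(q_cpp, q_ref, tolerance = 1e-5)
})

test_that("classifier gradients match finite differences of the reference", {
  set.seed(52)
  clf <- build_classifier(seed = 5)
  xs <- lapply(1:2, function(i) matrix(runif(128 * 128), 128, 128))
  y <- c(0, 1)
  res <- rpeseg:::cpp_encoder_loss_grad(unname(clf$weights),
                                        rpeseg:::stack_slices(xs, 128L), y)
  expect_equal(res$loss, ref_encoder_loss(clf$weights, xs, y), tolerance = 1e-5)
  h <- 1e-5
  # one high-gradient entry from a spread of layers (conv, pool edge, dense)
  for (ti in c("conv1a_w", "conv2b_w", "conv4b_b", "dense1_w", "dense4_b")) {
    g <- as.numeric(res$grads[[match(ti, names(clf$weights))]])
    j <- which.max(abs(g))
    wp <- clf$weights; wp[[ti]][j] <- wp[[ti]][j] + h
    wm <- clf$weights; wm[[ti]][j] <- wm[[ti]][j] - h
    fd <- (ref_encoder_loss(wp, xs, y) - ref_encoder_loss(wm, xs, y)) / (2 * h)
    expect_equal(g[j], fd, tolerance = 0.05)
  }
})

test_that("U-Net gradients match finite differences of the reference", {
  set.seed(53)
  un <- build_unet(seed = 6)
  tx <- lapply(1:2, function(i) matrix(runif(64 * 64), 64, 64))
  ty <- lapply(1:2, function(i) {
    m <- matrix(0, 64, 64); m[sample(4096, 250)] <- 1; m
  })
  res <- rpeseg:::cpp_unet_loss_grad(unname(un$weights),
                                     rpeseg:::stack_slices(tx, 64L),
                                     rpeseg:::stack_slices(ty, 64L), 1.0)
  expect_equal(res$loss, ref_unet_loss(un$weights, tx, ty), tolerance = 1e-5)
  h <- 1e-5
  for (ti in c("enc1a_w", "bott_b_w", "up1_w", "dec2b_b", "out_w")) {
    g <- as.numeric(res$grads[[match(ti, names(un$weights))]])
    j <- which.max(abs(g))
    wp <- un$weights; wp[[ti]][j] <- wp[[ti]][j] + h
    wm <- un$weights; wm[[ti]][j] <- wm[[ti]][j] - h
    fd <- (ref_unet_loss(wp, tx, ty) - ref_unet_loss(wm, tx, ty)) / (2 * h)
    expect_equal(g[j], fd, tolerance = 0.05)
  }
})

test_that("training is deterministic given seeds", {
  set.seed(54)
  xs <- lapply(1:12, function(i) matrix(runif(128 * 128), 128, 128))
  y <- rep(0:1, 6)
  f1 <- train_classifier(build_classifier(seed = 7), xs, y,
                         classify_train_config(epochs = 1, seed = 8))
  f2 <- train_classifier(build_classifier(seed = 7), xs, y,
                         classify_train_config(epochs = 1, seed = 8))
  expect_identical(f1$weights, f2$weights)
})
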