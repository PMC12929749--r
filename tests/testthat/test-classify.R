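test_that("moving average obeys the shrinking-edge rule", {
  expect_equal(moving_average(c(1, 0, 0, 0, 1), 3),
               c(0.5, 1 / 3, 0, 1 / 3, 0.5))
  x <- rnorm(10)
  expect_identical(moving_average(x, 1), x)
  expect_equal(moving_average(rep(0.7, 8), 5), rep(0.7, 8))
  expect_error(moving_average(x, 2), "odd")
})

test_that("moving average is linear and mean-preserving in the interior", {
  set.seed(31)
  a <- rnorm(30); b <- rnorm(30)
  expect_equal(moving_average(2 * a + 3 * b, 5),
               2 * moving_average(a, 5) + 3 * moving_average(b, 5))
  sm <- moving_average(a, 3)
  # interior elements are plain centered means
  for (i in 2:29) expect_equal(sm[i], mean(a[(i - 1):(i + 1)]))
})

test_that("Youden threshold uses midpoints and breaks ties downward", {
  t1 <- youden_threshold(c(0.2, 0.3, 0.7, 0.9), c(0, 0, 1, 1))
  expect_equal(as.numeric(t1), 0.5)
  expect_equal(attr(t1, "youden"), 1)

  t2 <- youden_threshold(c(0.1, 0.6, 0.4, 0.9), c(0, 0, 1, 1))
  expect_equal(as.numeric(t2), 0.25)
  expect_equal(attr(t2, "youden"), 0.5)

  expect_error(youden_threshold(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("Youden scan attains the brute-force maximum on random series", {
  set.seed(32)
  for (i in 1:1000) {
    n <- sample(4:20, 1)
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # induce ties sometimes
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    thr <- youden_threshold(scores, labels)
    expect_equal(attr(thr, "youden"), brute_youden_j(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("classifier builds are seeded and produce scalar scores", {
  a <- build_classifier(seed = 5)
  b <- build_classifier(seed = 5)
  x <- list(matrix(runif(128 * 128), 128, 128))
  expect_identical(predict_slices(a, x), predict_slices(b, x))
  p <- predict_slices(a, x)
  expect_length(p, 1L)
  expect_true(is.finite(p) && p > 0 && p < 1)
  d <- build_classifier(seed = 6)
  expect_false(identical(predict_slices(a, x), predict_slices(d, x)))
})

test_that("training runs the configured epochs and learns an easy cohort", {
  set.seed(33)
  cases <- lapply(41:44, easy_phantom)
  sel <- rpeseg:::select_training_slices(cases, "axial", 48)
  xs <- rpeseg:::preprocess_selected(cases, sel, "axial")
  clf <- build_classifier(seed = 1, view = "axial")

  same <- train_classifier(clf, xs, sel$label,
                           classify_train_config(epochs = 0))
  expect_identical(same$weights, clf$weights)

  fit <- train_classifier(clf, xs, sel$label,
                          classify_train_config(epochs = 3, seed = 2))
  expect_length(fit$history, 3L)
  expect_lt(fit$history[3], fit$history[1])

  expect_error(train_classifier(clf, xs, rep(1, length(xs)),
                                classify_train_config()),
               "both positive and negative")
})

test_that("classify_volume binarizes smoothed scores monotonically", {
  cs <- easy_phantom(45)
  clf <- build_classifier(seed = 3, view = "axial")
  lo <- classify_volume(clf, cs$volume, "axial", threshold = 0.2)
  hi <- classify_volume(clf, cs$volume, "axial", threshold = 0.9)
  expect_identical(nrow(lo), dim(cs$volume$data)[1])
  expect_equal(lo$label, as.integer(lo$smoothed >= 0.2))
  # raising the threshold can only switch labels off, never on
  expect_true(all(hi$label <= lo$label))
  expect_error(classify_volume(clf, cs$volume, "coronal"), "trained for")
})
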