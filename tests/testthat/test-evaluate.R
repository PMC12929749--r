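test_that("confusion counts are exact", {
  cc <- confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 0))
  expect_identical(unclass(cc)[c("tp", "fp", "tn", "fn")],
                   list(tp = 1L, fp = 1L, tn = 2L, fn = 0L))
  same <- confusion_counts(c(1, 0, 1), c(1, 0, 1))
  expect_identical(same$fp + same$fn, 0L)
  wrong <- confusion_counts(c(1, 0), c(0, 1))
  expect_identical(wrong$tp + wrong$tn, 0L)
  expect_error(confusion_counts(c(1, 0), c(1)), "lengths")
})

test_that("classification metrics reproduce the printed formulas", {
  cc <- structure(list(tp = 2L, fn = 1L, fp = 1L, tn = 6L),
                  class = "confusion_counts")
  m <- classification_metrics(cc)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$sensitivity, 2 / 3)
  expect_equal(m$specificity, 6 / 7)
  expect_equal(m$precision, 2 / 3)

  # the audit variant omits FP from the accuracy denominator
  expect_equal(classification_metrics(cc, formula = "as_printed")$accuracy,
               8 / 9)

  none <- structure(list(tp = 0L, fn = 2L, fp = 0L, tn = 3L),
                    class = "confusion_counts")
  expect_true(is.na(classification_metrics(none)$precision))

  perfect <- classification_metrics(confusion_counts(c(1, 0, 1), c(1, 0, 1)))
  expect_true(all(perfect == 1))
})

test_that("AUROC equals the exhaustive pairwise comparison", {
  expect_equal(auroc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  expect_equal(auroc(c(0.9, 0.1), c(0, 1)), 0)
  expect_true(is.na(auroc(c(0.3, 0.4), c(1, 1))))
  set.seed(91)
  for (i in 1:200) {
    n <- sample(5:25, 1)
    scores <- round(runif(n), sample(c(1, 6), 1))
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    expect_equal(auroc(scores, labels), pairwise_auroc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUROC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(92)
  scores <- runif(60); labels <- rbinom(60, 1, 0.4)
  expect_equal(auroc(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                              levels = c(0, 1),
                                              direction = "<"))))
})

test_that("volume agreement reproduces the error definitions", {
  perfect <- volume_agreement(c(1000, 2500), c(1000, 2500))
  expect_equal(perfect$pearson_r, 1)
  expect_equal(perfect$mae_mm3, 0)
  expect_equal(perfect$mre_pct, 0)

  doubled <- volume_agreement(c(500, 900, 1400), 2 * c(500, 900, 1400))
  expect_equal(doubled$mre_pct, 100)

  set.seed(93)
  real <- runif(30, 200, 30000); pred <- real * runif(30, 0.3, 2)
  va <- volume_agreement(real, pred)
  r_oracle <- sum((real - mean(real)) * (pred - mean(pred))) /
    sqrt(sum((real - mean(real))^2) * sum((pred - mean(pred))^2))
  expect_equal(va$pearson_r, r_oracle, tolerance = 1e-12)
  expect_equal(va$mae_mm3, mean(abs(pred - real)), tolerance = 1e-12)
  expect_error(volume_agreement(c(0, 10), c(1, 2)), "positive")
})

test_that("cohort summaries follow the stated conventions", {
  sm <- tibble::tibble(id = "p1", view = "axial", accuracy = 0.9,
                       sensitivity = 0.8, specificity = 0.95, precision = NA,
                       auroc = 0.99)
  dc <- tibble::tibble(id = c("p1", "p2", "p3"), view = "axial",
                       dice = c(0, 0.4, 0))
  s <- summarize_experiment(sm, dc)
  expect_true(all(s$classification$sd == 0))  # single patient: SD 0
  prec <- s$classification[s$classification$metric == "precision", ]
  expect_identical(prec$n, 0L)  # undefined excluded, not imputed
  expect_identical(s$segmentation$n_zero, 2L)
  expect_equal(s$segmentation$minimum, 0)
  expect_equal(s$segmentation$median, 0)

  flat <- summarize_experiment(sm, tibble::tibble(id = "p", view = "axial",
                                                  dice = 0.5))
  expect_equal(flat$segmentation$mean, 0.5)
  expect_equal(flat$segmentation$minimum, 0.5)
  expect_equal(flat$segmentation$maximum, 0.5)
})
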