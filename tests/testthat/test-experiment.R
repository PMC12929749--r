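test_that("folds partition patients as evenly as possible", {
  f10 <- make_folds(sprintf("p%02d", 1:10), k = 5, seed = 1)
  expect_identical(sort(as.integer(table(f10$fold))), rep(2L, 5))

  f11 <- make_folds(sprintf("p%02d", 1:11), k = 5, seed = 1)
  expect_identical(sort(as.integer(table(f11$fold))), c(2L, 2L, 2L, 2L, 3L))

  expect_identical(sort(f11$id), sprintf("p%02d", 1:11))  # exactly once each
  expect_identical(make_folds(sprintf("p%02d", 1:11), 5, seed = 9),
                   make_folds(sprintf("p%02d", 1:11), 5, seed = 9))
  expect_false(identical(f11$fold,
                         make_folds(sprintf("p%02d", 1:11), 5, seed = 2)$fold))
  expect_error(make_folds(c("a", "b"), k = 5), "fewer patients")
})

test_that("a YAML config round-trips through the reader", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("n_phantoms: 4", "folds: 2", "max_train_tiles: 12",
               "phantom:", "  in_plane: 64", "  lesion_contrast: 4",
               "classifier:", "  epochs: 1", "unet:", "  epochs: 2"), f)
  cfg <- read_experiment_config(f)
  expect_s3_class(cfg, "experiment_config")
  expect_identical(cfg$n_phantoms, 4L)
  expect_identical(cfg$phantom$in_plane, 64L)
  expect_identical(cfg$classifier$epochs, 1L)
  expect_identical(cfg$unet$epochs, 2L)
})

tiny_config <- function(output_dir = NULL) {
  experiment_config(
    n_phantoms = 5, phantom = phantom_spec(in_plane = 64, lesion_contrast = 3),
    folds = 2,
    classifier = classify_train_config(epochs = 1),
    unet = seg_train_config(epochs = 2),
    max_train_slices = 24, youden_volumes = 2, max_train_tiles = 8,
    output_dir = output_dir)
}

test_that("a small experiment emits complete, leakage-free results", {
  dir <- tempfile("run")
  ex <- suppressMessages(run_experiment(tiny_config(dir), seed = 5))

  # every patient evaluated once, in its own test fold only
  expect_identical(sort(unique(ex$slice_metrics$id)), sort(ex$folds$id))
  per_patient <- table(ex$slice_metrics$id)
  expect_true(all(per_patient == 3L))  # one row per view
  joined <- merge(ex$slice_metrics, ex$folds, by = "id")
  expect_identical(joined$fold.x, joined$fold.y)  # evaluated in own fold

  # four masks per patient, bounded Dice
  expect_identical(nrow(ex$dice), 4L * nrow(ex$folds))
  expect_true(all(ex$dice$dice >= 0 & ex$dice$dice <= 1))
  expect_setequal(unique(ex$dice$view),
                  c("axial", "coronal", "sagittal", "2.5d"))

  # volumes positive on the truth side; summaries and agreement present
  expect_true(all(ex$volumes$true_mm3 > 0))
  expect_identical(nrow(ex$volumes), nrow(ex$folds))
  expect_s3_class(ex$classification_summary, "tbl_df")
  expect_s3_class(ex$volume_agreement, "tbl_df")

  # thresholds recorded per fold and view
  expect_identical(nrow(ex$thresholds), 6L)

  # output files written
  for (f in c("folds.csv", "patient_metrics.csv", "dice.csv", "volumes.csv",
              "thresholds.csv", "segmentation_summary.csv", "log.csv"))
    expect_true(file.exists(file.path(dir, f)))

  # tidiers work on the result
  expect_s3_class(glance(ex), "tbl_df")
  expect_identical(nrow(glance(ex)), 1L)
  expect_true(all(c("id", "view", "metric", "value") %in% names(tidy(ex))))
})
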