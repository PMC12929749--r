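#' Configuration of an end-to-end cross-validated experiment
#'
#' Bundles every tunable of the pipeline. The defaults define the package's
#' desk-scale reference experiment: 25 lesion-positive phantoms at 128 x 128
#' in-plane with lesion contrast 3, five-fold cross-validation over patients,
#' the reference training recipes (5-epoch BCE classifier, 30-epoch Dice-loss
#' U-Net), moving-average window 3, and training-set Youden thresholds.
#'
#' Three knobs control desk-scale cost without changing the method:
#' `max_train_slices` (balanced per-view subsample of training slices;
#' `Inf` trains on every slice), `youden_volumes` (how many training volumes
#' are fully classified to estimate thresholds and to sample training tiles
#' from their predicted regions; `Inf` uses all), and `max_train_tiles`
#' (per-view cap on U-Net training tiles).
#'
#' @param n_phantoms Number of lesion-positive phantoms.
#' @param phantom A [phantom_spec()] for the cohort.
#' @param folds Number of cross-validation folds.
#' @param window Moving-average window (odd).
#' @param classifier A [classify_train_config()].
#' @param unet A [seg_train_config()].
#' @param max_train_slices Per-view cap on classifier training slices.
#' @param youden_volumes Training volumes used for threshold estimation and
#'   training-tile sampling.
#' @param max_train_tiles Per-view cap on U-Net training tiles.
#' @param tile_source `"predicted_region"` (sample training tiles from the
#'   classifiers' predicted regions, as at test time) or `"truth_region"`
#'   (sample from ground-truth slice labels).
#' @param stride,tile_size,frac_min Tile lattice and selection parameters.
#' @param abs_min Absolute tile-selection criterion; `NULL` scales the
#'   full-size value 1000 by `(in_plane / 512)^2`.
#' @param fusion Overlap fusion, `"mean"` or `"max"`.
#' @param seg_threshold Binarization threshold on fused probabilities.
#' @param auroc_scores Use `"smoothed"` (default) or `"raw"` scores for
#'   patient-wise AUROC.
#' @param output_dir Optional directory for CSV outputs.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(n_phantoms = 25L,
                              phantom = phantom_spec(in_plane = 128L,
                                                     lesion_contrast = 3),
                              folds = 5L,
                              window = 3L,
                              classifier = classify_train_config(),
                              unet = seg_train_config(),
                              max_train_slices = 120L,
                              youden_volumes = 6L,
                              max_train_tiles = 64L,
                              tile_source = c("predicted_region", "truth_region"),
                              stride = 32L, tile_size = 64L, frac_min = 1 / 3,
                              abs_min = NULL,
                              fusion = "mean", seg_threshold = 0.5,
                              auroc_scores = c("smoothed", "raw"),
                              output_dir = NULL) {
  structure(list(
    n_phantoms = as.integer(n_phantoms), phantom = phantom,
    folds = as.integer(folds), window = as.integer(window),
    classifier = classifier, unet = unet,
    max_train_slices = max_train_slices, youden_volumes = youden_volumes,
    max_train_tiles = max_train_tiles,
    tile_source = match.arg(tile_source),
    stride = as.integer(stride), tile_size = as.integer(tile_size),
    frac_min = frac_min, abs_min = abs_min,
    fusion = fusion, seg_threshold = seg_threshold,
    auroc_scores = match.arg(auroc_scores),
    output_dir = output_dir), class = "experiment_config")
}

effective_abs_min <- function(config) {
  if (!is.null(config$abs_min)) return(config$abs_min)
  1000 * (config$phantom$in_plane / 512)^2
}

#' Read an experiment configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [experiment_config()]; the nested
#' `phantom`, `classifier` and `unet` maps mirror [phantom_spec()],
#' [classify_train_config()] and [seg_train_config()].
#'
#' @param path YAML file path.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[setdiff(names(y), c("phantom", "classifier", "unet"))]
  if (!is.null(y$phantom)) args$phantom <- do.call(phantom_spec, y$phantom)
  if (!is.null(y$classifier))
    args$classifier <- do.call(classify_train_config, y$classifier)
  if (!is.null(y$unet)) args$unet <- do.call(seg_train_config, y$unet)
  do.call(experiment_config, args)
}

#' Assign patients to cross-validation folds
#'
#' Seeded permutation followed by round-robin assignment: folds are as even
#' as possible, every patient appears in exactly one test fold, and the same
#' seed always yields the same split.
#'
#' @param patient_ids Character vector of ids.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return Tibble with columns `id`, `fold`.
#' @export
#' @examples
#' make_folds(sprintf("p%02d", 1:11), k = 5, seed = 1)
make_folds <- function(patient_ids, k = 5L, seed = 1L) {
  if (length(patient_ids) < k) abort("fewer patients than folds.")
  if (anyDuplicated(patient_ids)) abort("patient ids must be unique.")
  perm <- withr::with_seed(as.integer(seed), sample(patient_ids))
  tibble::tibble(id = perm, fold = rep_len(seq_len(k), length(perm))) |>
    dplyr::arrange(.data$id)
}

# balanced, capped selection of training slice indices for one view
select_training_slices <- function(cases, view, max_slices) {
  pool <- dplyr::bind_rows(lapply(seq_along(cases), function(i) {
    lab <- slice_labels(cases[[i]]$mask, view)
    tibble::tibble(case = i, index = seq_along(lab), label = lab)
  }))
  pos <- pool[pool$label == 1L, ]
  neg <- pool[pool$label == 0L, ]
  n_pos <- min(nrow(pos), max(1L, floor(max_slices / 2)))
  n_neg <- min(nrow(neg), max_slices - n_pos)
  sel <- dplyr::bind_rows(
    pos[sample.int(nrow(pos), n_pos), ],
    neg[sample.int(nrow(neg), n_neg), ])
  sel[sample.int(nrow(sel)), ]
}

preprocess_selected <- function(cases, sel, view) {
  ext <- lapply(cases, function(cs) range(cs$volume$data))
  lapply(seq_len(nrow(sel)), function(j) {
    cs <- cases[[sel$case[j]]]
    preprocess_slice(slice_at(cs$volume$data, view, sel$index[j]),
                     ext[[sel$case[j]]][1], ext[[sel$case[j]]][2])
  })
}

# Balanced cap on training tiles. Tiles whose ground truth is entirely empty
# arise wherever the predicted region overshoots the true lesion extent; left
# in the majority they collapse Dice-loss training toward the all-empty
# prediction, so lesion-bearing tiles get at least half of the cap (the same
# balancing rule the slice sampler uses).
subsample_tiles <- function(tiles, truths, max_tiles) {
  n <- length(tiles)
  pos <- which(vapply(truths, function(m) any(m > 0), logical(1)))
  neg <- setdiff(seq_len(n), pos)
  if (n <= max_tiles) {
    keep <- seq_len(n)
  } else {
    n_pos <- min(length(pos), max(1L, floor(max_tiles / 2)))
    n_neg <- min(length(neg), max_tiles - n_pos)
    n_pos <- min(length(pos), max_tiles - n_neg)  # backfill if negatives scarce
    keep <- c(pos[sample.int(length(pos), n_pos)],
              if (n_neg > 0L) neg[sample.int(length(neg), n_neg)])
    keep <- keep[sample.int(length(keep))]
  }
  list(tiles = tiles[keep], truths = truths[keep])
}

#' Run the full coarse-to-fine experiment
#'
#' Generates (or accepts) a lesion-positive phantom cohort, splits patients
#' into folds, and per fold: trains the three per-view slice classifiers,
#' estimates per-view Youden thresholds from smoothed training-set
#' predictions, samples 64 x 64 training tiles around predicted (or
#' ground-truth) regions, trains the three per-view U-Nets, then predicts
#' every test patient end-to-end (classify, smooth, threshold, region, tiles,
#' segment, reassemble, majority vote) and evaluates classification,
#' segmentation and volume agreement. A failing fold is logged and skipped;
#' the remaining folds proceed.
#'
#' @param config An [experiment_config()].
#' @param seed Master seed; together with `config` it fully determines the
#'   run on a fixed single-threaded numeric backend.
#' @param cohort Optional pre-generated list of `phantom_case` objects
#'   (bypasses generation; ids must be unique).
#' @return An object of class `rpe_experiment`: tibbles `folds`,
#'   `slice_metrics`, `dice`, `volumes`, `regions`, `thresholds`, `log`,
#'   the two summary tables, `volume_agreement`, and `dice_volume_r`.
#' @export
run_experiment <- function(config = experiment_config(), seed = 1L,
                           cohort = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  pool <- withr::with_seed(as.integer(seed),
                           sample.int(.Machine$integer.max - 1L, 4096L))
  ctr <- new.env(); ctr$i <- 0L
  next_seed <- function() { ctr$i <- ctr$i + 1L; pool[ctr$i] }

  log_rows <- list()
  log_stage <- function(fold, stage, view = NA_character_, secs = NA_real_,
                        detail = "") {
    message(sprintf("[fold %s] %-18s %-8s %s%s", fold, stage, view,
                    if (is.na(secs)) "" else sprintf("%6.1fs ", secs), detail))
    log_rows[[length(log_rows) + 1L]] <<-
      tibble::tibble(fold = fold, stage = stage, view = view,
                     seconds = secs, detail = detail)
  }

  t0 <- proc.time()[3]
  if (is.null(cohort)) {
    cohort <- generate_cohort(config$n_phantoms, config$phantom,
                              seed = next_seed())
    log_stage(0L, "generate_cohort",
              detail = sprintf("%d phantoms", length(cohort)))
  }
  ids <- vapply(cohort, function(cs) cs$volume$id, character(1))
  names(cohort) <- ids
  folds <- make_folds(ids, k = config$folds, seed = next_seed())
  abs_min <- effective_abs_min(config)
  views <- plane_views()

  slice_metrics <- list(); dice_rows <- list(); vol_rows <- list()
  region_rows <- list(); thr_rows <- list(); score_rows <- list()

  for (f in sort(unique(folds$fold))) {
    fold_res <- tryCatch({
      test_ids <- folds$id[folds$fold == f]
      train_ids <- setdiff(ids, test_ids)
      train_cases <- cohort[train_ids]

      # --- slice classifiers -------------------------------------------------
      classifiers <- list()
      for (v in views) {
        tv <- proc.time()[3]
        sel <- withr::with_seed(next_seed(),
                                select_training_slices(train_cases, v,
                                                       config$max_train_slices))
        xs <- preprocess_selected(train_cases, sel, v)
        cfg <- config$classifier; cfg$seed <- next_seed()
        clf <- build_classifier(seed = next_seed(), view = v)
        clf <- train_classifier(clf, xs, sel$label, cfg)
        classifiers[[v]] <- clf
        log_stage(f, "train_classifier", v, proc.time()[3] - tv,
                  sprintf("%d slices (%d pos), final BCE %.4f",
                          length(xs), sum(sel$label),
                          clf$history[length(clf$history)]))
      }

      # --- Youden thresholds from smoothed training predictions --------------
      tv <- proc.time()[3]
      n_yv <- min(length(train_ids), config$youden_volumes)
      yv_ids <- withr::with_seed(next_seed(), sample(train_ids, n_yv))
      train_series <- list()
      thresholds <- numeric(0)
      for (v in views) {
        sc <- list(); lb <- list()
        for (id in yv_ids) {
          sss <- classify_volume(classifiers[[v]], cohort[[id]]$volume, v,
                                 threshold = 0.5, window = config$window)
          sc[[id]] <- sss$smoothed
          lb[[id]] <- slice_labels(cohort[[id]]$mask, v)
          train_series[[paste(v, id)]] <- list(view = v, id = id, sss = sss)
        }
        thr <- youden_threshold(unlist(sc), unlist(lb))
        thresholds[v] <- as.numeric(thr)
        thr_rows[[length(thr_rows) + 1L]] <-
          tibble::tibble(fold = f, view = v, threshold = as.numeric(thr),
                         youden_j = attr(thr, "youden"))
      }
      log_stage(f, "youden_thresholds", secs = proc.time()[3] - tv,
                detail = paste(sprintf("%s=%.3f", views, thresholds[views]),
                               collapse = " "))

      # --- training tiles ----------------------------------------------------
      tv <- proc.time()[3]
      tile_x <- stats::setNames(vector("list", 3), views)
      tile_y <- stats::setNames(vector("list", 3), views)
      for (id in yv_ids) {
        cs <- cohort[[id]]
        reg <- if (config$tile_source == "predicted_region") {
          lab <- lapply(views, function(v) {
            s <- train_series[[paste(v, id)]]$sss
            as.integer(s$smoothed >= thresholds[v])
          })
          build_region(lab[[1]], lab[[2]], lab[[3]])
        } else {
          build_region(slice_labels(cs$mask, "axial"),
                       slice_labels(cs$mask, "coronal"),
                       slice_labels(cs$mask, "sagittal"))
        }
        for (v in views) {
          cv <- collect_view_tiles(cs$volume, reg, v, mask = cs$mask,
                                   stride = config$stride,
                                   size = config$tile_size,
                                   frac_min = config$frac_min,
                                   abs_min = abs_min)
          tile_x[[v]] <- c(tile_x[[v]], cv$tiles)
          tile_y[[v]] <- c(tile_y[[v]], cv$truths)
        }
      }
      # fall back to ground-truth regions if a view collected no lesion tile
      for (v in views) {
        has_pos <- any(vapply(tile_y[[v]], function(m) any(m > 0), logical(1)))
        if (length(tile_x[[v]]) == 0L || !has_pos) {
          log_stage(f, "tile_fallback", v,
                    detail = "no lesion tile from predicted regions; using truth regions")
          for (id in yv_ids) {
            cs <- cohort[[id]]
            reg <- build_region(slice_labels(cs$mask, "axial"),
                                slice_labels(cs$mask, "coronal"),
                                slice_labels(cs$mask, "sagittal"))
            cv <- collect_view_tiles(cs$volume, reg, v, mask = cs$mask,
                                     stride = config$stride,
                                     size = config$tile_size,
                                     frac_min = config$frac_min,
                                     abs_min = abs_min)
            tile_x[[v]] <- c(tile_x[[v]], cv$tiles)
            tile_y[[v]] <- c(tile_y[[v]], cv$truths)
          }
        }
      }
      log_stage(f, "sample_tiles", secs = proc.time()[3] - tv,
                detail = paste(sprintf("%s=%d", views,
                                       vapply(tile_x[views], length, integer(1))),
                               collapse = " "))

      # --- U-Nets ------------------------------------------------------------
      unets <- list()
      for (v in views) {
        tv <- proc.time()[3]
        sub <- withr::with_seed(next_seed(),
                                subsample_tiles(tile_x[[v]], tile_y[[v]],
                                                config$max_train_tiles))
        cfg <- config$unet; cfg$seed <- next_seed()
        un <- build_unet(seed = next_seed(), view = v)
        un <- train_unet(un, sub$tiles, sub$truths, cfg)
        unets[[v]] <- un
        log_stage(f, "train_unet", v, proc.time()[3] - tv,
                  sprintf("%d tiles, final Dice loss %.4f",
                          length(sub$tiles), un$history[length(un$history)]))
      }

      # --- test patients -----------------------------------------------------
      for (id in test_ids) {
        tv <- proc.time()[3]
        cs <- cohort[[id]]
        series <- lapply(views, function(v)
          classify_volume(classifiers[[v]], cs$volume, v,
                          threshold = thresholds[v], window = config$window))
        names(series) <- views
        region <- build_region(series$axial$label, series$coronal$label,
                               series$sagittal$label)
        masks <- lapply(views, function(v)
          predict_view_mask(unets[[v]], cs$volume, region, v,
                            threshold = config$seg_threshold,
                            stride = config$stride, size = config$tile_size,
                            frac_min = config$frac_min, abs_min = abs_min,
                            fusion = config$fusion))
        names(masks) <- views
        vote <- majority_vote(masks$coronal, masks$sagittal, masks$axial)

        for (v in views) {
          truth_lab <- slice_labels(cs$mask, v)
          cm <- classification_metrics(confusion_counts(series[[v]]$label,
                                                        truth_lab))
          sc <- if (config$auroc_scores == "smoothed")
            series[[v]]$smoothed else series[[v]]$raw
          slice_metrics[[length(slice_metrics) + 1L]] <-
            dplyr::bind_cols(tibble::tibble(id = id, fold = f, view = v),
                             cm, tibble::tibble(auroc = auroc(sc, truth_lab)))
          score_rows[[length(score_rows) + 1L]] <-
            dplyr::mutate(series[[v]], id = id, fold = f, .before = 1)
        }
        dmask <- c(masks, list(`2.5d` = vote))
        dvals <- vapply(dmask, dice_coefficient, numeric(1), truth = cs$mask)
        for (v in names(dmask))
          dice_rows[[length(dice_rows) + 1L]] <-
            tibble::tibble(id = id, fold = f, view = v, dice = dvals[[v]])
        bbox_dice <- dice_coefficient(
          region_mask(region, cs$volume$spacing, dim(cs$volume$data)), cs$mask)
        region_rows[[length(region_rows) + 1L]] <-
          dplyr::mutate(region_summary(region, id), fold = f,
                        bbox_dice = bbox_dice,
                        lesion_in_region_pct =
                          if (region$voxel_count > 0)
                            100 * sum(region_mask(region, cs$volume$spacing,
                                                  dim(cs$volume$data))$data *
                                      cs$mask$data) / region$voxel_count
                          else 0)
        vol_rows[[length(vol_rows) + 1L]] <-
          tibble::tibble(id = id, fold = f,
                         true_mm3 = mask_volume_mm3(cs$mask)$mm3,
                         pred_mm3 = mask_volume_mm3(masks$axial)$mm3)
        log_stage(f, "predict_test", id, proc.time()[3] - tv,
                  sprintf("axial Dice %.3f", dvals[["axial"]]))
      }
      TRUE
    }, error = function(e) {
      log_stage(f, "fold_failed", detail = conditionMessage(e))
      FALSE
    })
    invisible(fold_res)
  }

  slice_metrics <- dplyr::bind_rows(slice_metrics)
  dice_tbl <- dplyr::bind_rows(dice_rows)
  volumes <- dplyr::bind_rows(vol_rows)
  regions <- dplyr::bind_rows(region_rows)
  thresholds_tbl <- dplyr::bind_rows(thr_rows)
  scores_tbl <- dplyr::bind_rows(score_rows)
  summaries <- summarize_experiment(slice_metrics,
                                    dplyr::select(dice_tbl, -"fold"))
  vol_agree <- if (nrow(volumes)) volume_agreement(volumes$true_mm3,
                                                   volumes$pred_mm3) else NULL
  axial_dice <- dice_tbl[dice_tbl$view == "axial", ]
  dv <- dplyr::inner_join(axial_dice, volumes, by = c("id", "fold"))
  dice_volume_r <- if (nrow(dv) >= 3 && sd(dv$dice) > 0)
    cor(dv$true_mm3, dv$dice) else NA_real_

  out <- structure(list(
    folds = folds, slice_metrics = slice_metrics, dice = dice_tbl,
    volumes = volumes, regions = regions, thresholds = thresholds_tbl,
    slice_scores = scores_tbl,
    classification_summary = summaries$classification,
    segmentation_summary = summaries$segmentation,
    volume_agreement = vol_agree, dice_volume_r = dice_volume_r,
    log = dplyr::bind_rows(log_rows), config = config, seed = seed,
    elapsed_s = proc.time()[3] - t0), class = "rpe_experiment")

  if (!is.null(config$output_dir)) write_experiment(out, config$output_dir)
  out
}

write_experiment <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(tbl, nm) if (!is.null(tbl) && nrow(tbl))
    write.csv(tbl, file.path(dir, nm), row.names = FALSE)
  wr(x$folds, "folds.csv")
  wr(x$slice_metrics, "patient_metrics.csv")
  wr(x$dice, "dice.csv")
  wr(x$volumes, "volumes.csv")
  wr(x$regions, "regions.csv")
  wr(x$thresholds, "thresholds.csv")
  wr(x$slice_scores, "slice_scores.csv")
  wr(x$classification_summary, "classification_summary.csv")
  wr(x$segmentation_summary, "segmentation_summary.csv")
  wr(x$volume_agreement, "volume_agreement.csv")
  wr(x$log, "log.csv")
  invisible(dir)
}

#' @export
print.rpe_experiment <- function(x, ...) {
  cat(sprintf("<rpe_experiment>  %d patients, %d folds, %.1f min\n",
              nrow(x$folds), max(x$folds$fold), x$elapsed_s / 60))
  au <- x$classification_summary[x$classification_summary$metric == "auroc", ]
  if (nrow(au))
    cat("  patient-wise AUROC: ",
        paste(sprintf("%s %.3f", au$view, au$mean), collapse = ", "), "\n")
  if (nrow(x$segmentation_summary))
    cat("  mean Dice:          ",
        paste(sprintf("%s %.3f", x$segmentation_summary$view,
                      x$segmentation_summary$mean), collapse = ", "), "\n")
  if (!is.null(x$volume_agreement))
    cat(sprintf("  volume agreement:   r %.3f, MAE %.0f mm^3, MRE %.1f%%\n",
                x$volume_agreement$pearson_r, x$volume_agreement$mae_mm3,
                x$volume_agreement$mre_pct))
  invisible(x)
}
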