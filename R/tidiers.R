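# broom-style tidiers for fitted models and experiment results

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a trained slice classifier
#'
#' @param x An `rpe_classifier`.
#' @param ... Unused.
#' @return Tibble with one row per training epoch (`epoch`, `loss`).
#' @export
tidy.rpe_classifier <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$history %||% numeric(0)),
                 loss = x$history %||% numeric(0))
}

#' @rdname tidy.rpe_classifier
#' @export
tidy.rpe_unet <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$history %||% numeric(0)),
                 loss = x$history %||% numeric(0))
}

#' One-row summary of a trained model
#'
#' @param x An `rpe_classifier` or `rpe_unet`.
#' @param ... Unused.
#' @return Tibble with parameter count, view, epochs trained and final loss.
#' @export
glance.rpe_classifier <- function(x, ...) {
  tibble::tibble(view = x$view %||% NA_character_, n_params = x$n_params,
                 epochs = length(x$history %||% numeric(0)),
                 final_loss = if (is.null(x$history)) NA_real_
                 else x$history[length(x$history)])
}

#' @rdname glance.rpe_classifier
#' @export
glance.rpe_unet <- glance.rpe_classifier

#' Tidy an experiment: per-patient metrics in long form
#'
#' @param x An `rpe_experiment`.
#' @param ... Unused.
#' @return Tibble with columns `id`, `fold`, `view`, `metric`, `value`
#'   covering the five classification metrics and the Dice coefficients.
#' @export
tidy.rpe_experiment <- function(x, ...) {
  cls <- x$slice_metrics |>
    tidyr::pivot_longer(dplyr::all_of(c("accuracy", "sensitivity",
                                        "specificity", "precision", "auroc")),
                        names_to = "metric", values_to = "value")
  seg <- x$dice |> dplyr::mutate(metric = "dice") |>
    dplyr::rename(value = "dice")
  dplyr::bind_rows(cls, seg)
}

#' One-row summary of an experiment
#'
#' @param x An `rpe_experiment`.
#' @param ... Unused.
#' @return Tibble with cohort size, per-view mean AUROC, axial and 2.5D mean
#'   Dice, volume-agreement statistics and the Dice-volume correlation.
#' @export
glance.rpe_experiment <- function(x, ...) {
  au <- function(v) {
    s <- x$classification_summary
    m <- s$mean[s$metric == "auroc" & s$view == v]
    if (length(m)) m else NA_real_
  }
  dice_mean <- function(v) {
    s <- x$segmentation_summary
    m <- s$mean[s$view == v]
    if (length(m)) m else NA_real_
  }
  tibble::tibble(
    n_patients = nrow(x$folds), n_folds = max(x$folds$fold),
    auroc_axial = au("axial"), auroc_coronal = au("coronal"),
    auroc_sagittal = au("sagittal"),
    dice_axial = dice_mean("axial"), dice_2p5d = dice_mean("2.5d"),
    volume_r = if (is.null(x$volume_agreement)) NA_real_
    else x$volume_agreement$pearson_r,
    volume_mae_mm3 = if (is.null(x$volume_agreement)) NA_real_
    else x$volume_agreement$mae_mm3,
    volume_mre_pct = if (is.null(x$volume_agreement)) NA_real_
    else x$volume_agreement$mre_pct,
    dice_volume_r = x$dice_volume_r,
    elapsed_min = x$elapsed_s / 60)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
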