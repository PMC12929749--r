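# ggplot2 graphics for the main result types

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a per-slice score series
#'
#' Raw and smoothed classifier scores along the slice index, the decision
#' threshold, and the binarized labels.
#'
#' @param object A `slice_score_series` from [classify_volume()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.slice_score_series <- function(object, ...) {
  thr <- attr(object, "threshold")
  df <- tidyr::pivot_longer(tibble::as_tibble(object),
                            dplyr::all_of(c("raw", "smoothed")),
                            names_to = "series", values_to = "score")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$score,
                                   linetype = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = thr, colour = "red3") +
    ggplot2::geom_rug(data = tibble::as_tibble(object)[object$label == 1L, ],
                      ggplot2::aes(x = .data$index), inherit.aes = FALSE,
                      sides = "b") +
    ggplot2::labs(x = paste(object$view[1], "slice index"), y = "score",
                  title = attr(object, "id")) +
    ggplot2::theme_minimal()
}

#' Plot a phantom case
#'
#' The axial slice through the lesion centroid with the ground-truth contour.
#'
#' @param object A `phantom_case`.
#' @param z Axial slice to show; defaults to the lesion's central slice.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phantom_case <- function(object, z = NULL, ...) {
  if (is.null(z)) {
    zs <- which(apply(object$mask$data, 1, max) > 0)
    z <- if (length(zs)) zs[ceiling(length(zs) / 2)] else
      ceiling(dim(object$volume$data)[1] / 2)
  }
  img <- object$volume$data[z, , ]
  df <- tidyr::expand_grid(y = seq_len(nrow(img)), x = seq_len(ncol(img))) |>
    dplyr::mutate(intensity = as.numeric(img),
                  lesion = as.numeric(object$mask$data[z, , ]))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("%s, axial slice %d", object$volume$id, z)) +
    ggplot2::theme_void()
  if (any(df$lesion > 0))
    p <- p + ggplot2::geom_contour(ggplot2::aes(z = .data$lesion),
                                   breaks = 0.5, colour = "red")
  p
}

#' Plot experiment results
#'
#' @param object An `rpe_experiment`.
#' @param type `"dice"` (per-view Dice distributions), `"auroc"`
#'   (per-view patient AUROC) or `"volume"` (real vs predicted volume).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rpe_experiment <- function(object,
                                    type = c("dice", "auroc", "volume"), ...) {
  type <- match.arg(type)
  if (type == "dice") {
    ggplot2::ggplot(object$dice,
                    ggplot2::aes(x = .data$view, y = .data$dice)) +
      ggplot2::geom_boxplot(outlier.shape = NA) +
      ggplot2::geom_jitter(width = 0.15, alpha = 0.5) +
      ggplot2::labs(y = "patient-wise Dice", x = NULL) +
      ggplot2::theme_minimal()
  } else if (type == "auroc") {
    ggplot2::ggplot(object$slice_metrics,
                    ggplot2::aes(x = .data$view, y = .data$auroc)) +
      ggplot2::geom_boxplot(outlier.shape = NA) +
      ggplot2::geom_jitter(width = 0.15, alpha = 0.5) +
      ggplot2::labs(y = "patient-wise AUROC", x = NULL) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$volumes,
                    ggplot2::aes(x = .data$true_mm3, y = .data$pred_mm3)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
      ggplot2::geom_point() +
      ggplot2::labs(x = "real lesion volume (mm^3)",
                    y = "predicted lesion volume (mm^3)") +
      ggplot2::theme_minimal()
  }
}
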