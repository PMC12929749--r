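#' Confusion counts for binary predictions
#'
#' @param pred_labels,true_labels Equal-length 0/1 vectors.
#' @return A list of class `confusion_counts` with `tp`, `fn`, `fp`, `tn`.
#' @export
#' @examples
#' confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 0))
confusion_counts <- function(pred_labels, true_labels) {
  if (length(pred_labels) != length(true_labels)) abort("lengths differ.")
  p <- as.integer(pred_labels); t <- as.integer(true_labels)
  if (!all(p %in% 0:1) || !all(t %in% 0:1)) abort("labels must be binary 0/1.")
  structure(list(tp = sum(p == 1L & t == 1L), fn = sum(p == 0L & t == 1L),
                 fp = sum(p == 1L & t == 0L), tn = sum(p == 0L & t == 0L)),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, precision
#' `TP/(TP+FP)`, and accuracy `(TP+TN)/(TP+FN+FP+TN)`. Metrics with a zero
#' denominator are returned as `NA` ("undefined") and are excluded from
#' cohort means downstream rather than imputed. `formula = "as_printed"`
#' switches accuracy to the variant omitting FP from the denominator, kept
#' for auditability.
#'
#' @param counts A [confusion_counts()] result.
#' @param formula `"standard"` (default) or `"as_printed"`.
#' @return One-row tibble with `accuracy`, `sensitivity`, `specificity`,
#'   `precision`.
#' @export
classification_metrics <- function(counts, formula = c("standard", "as_printed")) {
  formula <- match.arg(formula)
  stopifnot(inherits(counts, "confusion_counts"))
  sdiv <- function(num, den) if (den == 0) NA_real_ else num / den
  acc_den <- if (formula == "standard")
    counts$tp + counts$fn + counts$fp + counts$tn
  else counts$tp + counts$fn + counts$tn
  tibble::tibble(
    accuracy = sdiv(counts$tp + counts$tn, acc_den),
    sensitivity = sdiv(counts$tp, counts$tp + counts$fn),
    specificity = sdiv(counts$tn, counts$tn + counts$fp),
    precision = sdiv(counts$tp, counts$tp + counts$fp))
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a uniformly random positive
#' outscores a uniformly random negative, with ties counted one half.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels.
#' @return AUROC in `[0, 1]`, or `NA` when only one class is present.
#' @export
#' @examples
#' auroc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) abort("lengths differ.")
  npos <- sum(labels == 1L); nneg <- sum(labels == 0L)
  if (npos == 0L || nneg == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Agreement between real and predicted lesion volumes
#'
#' Pearson correlation on the raw pairs, mean absolute error in mm^3, and
#' mean relative error in percent (`mean(|pred - real| / real) * 100`).
#' Real volumes must be positive (only lesion-positive patients are
#' segmented), otherwise the relative error is undefined.
#'
#' @param real_mm3,predicted_mm3 Paired numeric vectors; `real_mm3 > 0`.
#' @return One-row tibble with `pearson_r`, `mae_mm3`, `mre_pct`, `n`.
#' @export
#' @examples
#' volume_agreement(c(1000, 2000, 4000), c(900, 2400, 3500))
volume_agreement <- function(real_mm3, predicted_mm3) {
  if (length(real_mm3) != length(predicted_mm3)) abort("lengths differ.")
  if (any(real_mm3 <= 0))
    abort("real volumes must be positive (lesion-positive patients only).")
  r <- if (length(real_mm3) >= 2 && sd(real_mm3) > 0 && sd(predicted_mm3) > 0)
    cor(real_mm3, predicted_mm3) else NA_real_
  tibble::tibble(
    pearson_r = r,
    mae_mm3 = mean(abs(predicted_mm3 - real_mm3)),
    mre_pct = mean(abs(predicted_mm3 - real_mm3) / real_mm3) * 100,
    n = length(real_mm3))
}

#' Summarize per-patient metrics across the cohort
#'
#' Produces the two standard summary tables: per-view mean and standard
#' deviation of the five slice-classification metrics, and per-view mean,
#' SD, minimum, median and maximum of the patient-wise Dice coefficients
#' together with the number of patients at Dice 0. Undefined (`NA`) metrics
#' are excluded from means; a single-patient SD is reported as 0.
#'
#' @param slice_metrics Tibble with columns `id`, `view`, `accuracy`,
#'   `sensitivity`, `specificity`, `precision`, `auroc` (one row per patient
#'   and view).
#' @param dice Tibble with columns `id`, `view`, `dice` (views may include
#'   `"2.5d"`).
#' @return List with tibbles `classification` and `segmentation`.
#' @export
summarize_experiment <- function(slice_metrics, dice) {
  sd0 <- function(x) { x <- x[!is.na(x)]; if (length(x) <= 1L) 0 else sd(x) }
  mean_na <- function(x) mean(x, na.rm = TRUE)
  classification <- slice_metrics |>
    tidyr::pivot_longer(dplyr::all_of(c("accuracy", "sensitivity",
                                        "specificity", "precision", "auroc")),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$view, .data$metric) |>
    dplyr::summarise(mean = mean_na(.data$value), sd = sd0(.data$value),
                     n = sum(!is.na(.data$value)), .groups = "drop")
  segmentation <- dice |>
    dplyr::group_by(.data$view) |>
    dplyr::summarise(mean = mean_na(.data$dice), sd = sd0(.data$dice),
                     minimum = min(.data$dice), median = median(.data$dice),
                     maximum = max(.data$dice),
                     n_zero = sum(.data$dice == 0), n = dplyr::n(),
                     .groups = "drop")
  list(classification = classification, segmentation = segmentation)
}
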