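#' Build the slice-classification network
#'
#' A U-Net-encoder style classifier taking one 128 x 128 x 1 slice and
#' returning a single probability: four stages of paired 3 x 3 convolutions
#' (16, 32, 64, 128 filters) each followed by max pooling, then four dense
#' layers (128, 64, 32, 1) with a sigmoid output. The reference architecture
#' has exactly 565,873 trainable parameters.
#'
#' @param seed Integer seed for the Glorot-uniform initialization; two builds
#'   with the same seed produce identical weights.
#' @param view Optional view tag (`"axial"`, `"coronal"`, `"sagittal"`)
#'   recording which slice stack the model is meant for.
#' @return An object of class `rpe_classifier` with fields `weights`, `view`,
#'   `n_params`, `history`.
#' @export
#' @examples
#' clf <- build_classifier(seed = 1)
#' n_parameters(clf)  # 565873
build_classifier <- function(seed = NULL, view = NULL) {
  if (!is.null(view)) view <- match.arg(view, plane_views())
  w <- with_seed_if(seed, encoder_init_weights())
  m <- structure(list(weights = w, view = view, seed = seed, history = NULL),
                 class = "rpe_classifier")
  m$n_params <- n_parameters(m)
  m
}

#' @export
print.rpe_classifier <- function(x, ...) {
  cat(sprintf("<rpe_classifier%s>  %s parameters%s\n",
              if (is.null(x$view)) "" else paste0(" [", x$view, "]"),
              format(x$n_params, big.mark = ","),
              if (is.null(x$history)) " (untrained)" else
                sprintf(", trained %d epochs (final BCE %.4f)",
                        length(x$history), x$history[length(x$history)])))
  invisible(x)
}

#' Training configuration for the slice classifier
#'
#' Defaults follow the reference training recipe: binary cross-entropy loss,
#' Adam with learning rate 0.001, five epochs. Batch size and per-epoch
#' shuffling are implementation choices (seeded); the default batch of 8
#' suits the desk-scale subsampled training sets, where a large batch would
#' leave too few optimizer steps within the fixed epoch budget.
#'
#' @param epochs Number of passes over the training slices.
#' @param learning_rate Adam learning rate.
#' @param batch_size Mini-batch size.
#' @param seed Seed for shuffling.
#' @return A list of class `classify_train_config`.
#' @export
classify_train_config <- function(epochs = 5L, learning_rate = 0.001,
                                  batch_size = 8L, seed = NULL) {
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), seed = seed),
            class = "classify_train_config")
}

#' Train the slice classifier
#'
#' Runs exactly `config$epochs` passes of mini-batch Adam on binary
#' cross-entropy. The training set must contain both classes: a single-class
#' set would make the downstream Youden threshold selection degenerate.
#'
#' @param model An `rpe_classifier`.
#' @param slices List of preprocessed 128 x 128 matrices (see
#'   [preprocess_slice()]).
#' @param labels 0/1 vector, one per slice.
#' @param config A [classify_train_config()].
#' @return The model with updated weights and a per-epoch loss `history`.
#' @export
train_classifier <- function(model, slices, labels,
                             config = classify_train_config()) {
  stopifnot(inherits(model, "rpe_classifier"))
  labels <- as.numeric(labels)
  if (length(slices) != length(labels))
    abort("`slices` and `labels` lengths differ.")
  if (length(unique(labels)) < 2L && config$epochs > 0L)
    abort("training set must contain both positive and negative slices.")
  if (config$epochs == 0L) return(model)
  x <- stack_slices(slices, 128L)
  perms <- with_seed_if(config$seed, make_perms(config$epochs, length(labels)))
  fit <- cpp_encoder_train(unname(model$weights), x, labels, perms,
                           config$learning_rate, config$batch_size)
  model$weights <- stats::setNames(fit$weights, names(model$weights))
  model$history <- c(model$history, as.numeric(fit$epoch_loss))
  model
}

#' Raw classifier scores for a set of preprocessed slices
#'
#' @param model An `rpe_classifier`.
#' @param slices List of 128 x 128 matrices.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict_slices <- function(model, slices) {
  stopifnot(inherits(model, "rpe_classifier"))
  as.numeric(cpp_encoder_predict(unname(model$weights), stack_slices(slices, 128L)))
}

#' Centered moving average with shrinking edges
#'
#' Smooths an ordered per-slice score series with a centered mean of odd
#' width; at the series ends the window truncates to the available
#' neighbours. Suppresses isolated misclassifications before thresholding.
#'
#' @param scores Numeric vector.
#' @param window Odd integer >= 1.
#' @return Smoothed vector of the same length.
#' @export
#' @examples
#' moving_average(c(1, 0, 0, 0, 1), window = 3)  # 0.5, 1/3, 0, 1/3, 0.5
moving_average <- function(scores, window = 3L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    abort("`window` must be an odd integer >= 1.")
  n <- length(scores)
  if (window == 1L || n == 0L) return(scores)
  half <- window %/% 2L
  cs <- cumsum(c(0, scores))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Maximal Youden-index threshold
#'
#' Scans candidate cutpoints (midpoints between adjacent sorted unique scores
#' plus the extremes) and returns the threshold maximizing
#' `J = sensitivity + specificity - 1` under the classification rule
#' `score >= threshold`. Ties are broken toward the lower threshold.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels; both classes must be present.
#' @return The selected threshold, with the achieved index in attribute
#'   `"youden"`.
#' @export
#' @examples
#' youden_threshold(c(0.2, 0.3, 0.7, 0.9), c(0, 0, 1, 1))  # 0.5
youden_threshold <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) abort("lengths differ.")
  if (length(unique(labels)) < 2L)
    abort("both classes must be present to select a threshold.")
  u <- sort(unique(scores))
  cand <- c(u[1L],                              # classify everything positive
            if (length(u) > 1L) (u[-length(u)] + u[-1L]) / 2,
            u[length(u)] + 1)                   # classify everything negative
  npos <- sum(labels == 1L); nneg <- sum(labels == 0L)
  best_j <- -Inf; best_t <- cand[1L]
  for (t in cand) {
    pred <- scores >= t
    j <- sum(pred & labels == 1L) / npos + sum(!pred & labels == 0L) / nneg - 1
    if (j > best_j + 1e-12) { best_j <- j; best_t <- t }
  }
  structure(best_t, youden = best_j)
}

#' Classify every slice of a volume along one view
#'
#' Preprocesses all slices of the view, scores them with the trained
#' classifier, smooths the ordered score series with a centered moving
#' average, and binarizes at the supplied threshold (`smoothed >= threshold`).
#'
#' @param model A trained `rpe_classifier` for this view.
#' @param volume An [image_volume].
#' @param view One of the three anatomical views; must match `model$view`
#'   when that is set.
#' @param threshold Scalar decision threshold (typically the training-set
#'   Youden threshold).
#' @param window Moving-average width (odd).
#' @return A tibble of class `slice_score_series` with columns `view`,
#'   `index`, `raw`, `smoothed`, `label`, and attributes `threshold`,
#'   `window`, `id`.
#' @export
classify_volume <- function(model, volume, view = plane_views(),
                            threshold = 0.5, window = 3L) {
  view <- match.arg(view)
  stopifnot(inherits(model, "rpe_classifier"), inherits(volume, "image_volume"))
  if (!is.null(model$view) && !identical(model$view, view))
    abort(sprintf("model was trained for the %s view, not %s.", model$view, view))
  vmin <- min(volume$data); vmax <- max(volume$data)
  slices <- lapply(extract_slices(volume, view), preprocess_slice,
                   volume_min = vmin, volume_max = vmax)
  raw <- predict_slices(model, slices)
  smoothed <- moving_average(raw, window)
  out <- tibble::tibble(view = view, index = seq_along(raw), raw = raw,
                        smoothed = smoothed,
                        label = as.integer(smoothed >= threshold))
  attr(out, "threshold") <- threshold
  attr(out, "window") <- window
  attr(out, "id") <- volume$id
  class(out) <- c("slice_score_series", class(out))
  out
}
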