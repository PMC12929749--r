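#' Build the 64 x 64 tile segmentation U-Net
#'
#' A compact U-Net: two encoder stages of paired 3 x 3 convolutions (16 then
#' 32 filters) with max pooling, a 64-filter bottleneck, and a decoder of
#' 2 x 2 transpose convolutions whose outputs are concatenated with the
#' corresponding encoder activations (two skip connections), closed by a
#' 1 x 1 sigmoid head returning a per-pixel probability mask of the input
#' size. The reference architecture has exactly 116,753 trainable parameters.
#'
#' @param seed Integer seed for the Glorot-uniform initialization.
#' @param view Optional view tag.
#' @return An object of class `rpe_unet`.
#' @export
#' @examples
#' unet <- build_unet(seed = 1)
#' n_parameters(unet)  # 116753
build_unet <- function(seed = NULL, view = NULL) {
  if (!is.null(view)) view <- match.arg(view, plane_views())
  w <- with_seed_if(seed, unet_init_weights())
  m <- structure(list(weights = w, view = view, seed = seed, history = NULL),
                 class = "rpe_unet")
  m$n_params <- n_parameters(m)
  m
}

#' @export
print.rpe_unet <- function(x, ...) {
  cat(sprintf("<rpe_unet%s>  %s parameters%s\n",
              if (is.null(x$view)) "" else paste0(" [", x$view, "]"),
              format(x$n_params, big.mark = ","),
              if (is.null(x$history)) " (untrained)" else
                sprintf(", trained %d epochs (final Dice loss %.4f)",
                        length(x$history), x$history[length(x$history)])))
  invisible(x)
}

#' Training configuration for the tile U-Net
#'
#' Defaults follow the reference recipe: soft Dice loss
#' `1 - (2 * sum(p q) + eps) / (sum(p) + sum(q) + eps)`, Adam with learning
#' rate 0.001, 30 epochs. The smoothing constant guards the empty-empty case
#' only and must stay small: on 64 x 64 tiles any `eps` of order 1 turns the
#' all-empty prediction into a local minimum of the loss whenever the lesion
#' covers fewer than about `sqrt(4096)` pixels, and training reliably falls
#' into it (see the package vignette).
#'
#' @param epochs Number of passes over the training tiles.
#' @param learning_rate Adam learning rate.
#' @param batch_size Mini-batch size.
#' @param epsilon Dice smoothing constant.
#' @param seed Seed for shuffling.
#' @return A list of class `seg_train_config`.
#' @export
seg_train_config <- function(epochs = 30L, learning_rate = 0.001,
                             batch_size = 8L, epsilon = 1e-6, seed = NULL) {
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), epsilon = epsilon,
                 seed = seed),
            class = "seg_train_config")
}

tile_pixels <- function(tiles) {
  lapply(tiles, function(t) if (is.list(t)) t$pixels else t)
}

#' Train the tile U-Net
#'
#' Runs `config$epochs` passes of mini-batch Adam on the soft Dice loss.
#' At least one ground-truth tile must contain positive pixels: with every
#' target empty the Dice loss carries no usable signal.
#'
#' @param model An `rpe_unet`.
#' @param tiles List of 64 x 64 input matrices (or tile objects from
#'   [sample_tiles()]).
#' @param truth_tiles List of congruent 0/1 ground-truth matrices.
#' @param config A [seg_train_config()].
#' @return The model with updated weights and per-epoch loss `history`.
#' @export
train_unet <- function(model, tiles, truth_tiles, config = seg_train_config()) {
  stopifnot(inherits(model, "rpe_unet"))
  xs <- tile_pixels(tiles); ys <- tile_pixels(truth_tiles)
  if (length(xs) != length(ys)) abort("`tiles` and `truth_tiles` lengths differ.")
  if (!any(vapply(ys, function(m) any(m > 0), logical(1))))
    abort("all ground-truth tiles are empty; the Dice loss is degenerate.")
  if (config$epochs == 0L) return(model)
  x <- stack_slices(xs, 64L)
  y <- stack_slices(ys, 64L)
  perms <- with_seed_if(config$seed, make_perms(config$epochs, length(xs)))
  fit <- cpp_unet_train(unname(model$weights), x, y, perms,
                        config$learning_rate, config$batch_size, config$epsilon)
  model$weights <- stats::setNames(fit$weights, names(model$weights))
  model$history <- c(model$history, as.numeric(fit$epoch_loss))
  model
}

#' Per-pixel probability predictions for a set of tiles
#'
#' @param model An `rpe_unet`.
#' @param tiles List of 64 x 64 matrices or tile objects.
#' @return List of 64 x 64 probability matrices.
#' @export
predict_tiles <- function(model, tiles) {
  stopifnot(inherits(model, "rpe_unet"))
  xs <- tile_pixels(tiles)
  if (length(xs) == 0L) return(list())
  p <- cpp_unet_predict(unname(model$weights), stack_slices(xs, 64L))
  lapply(seq_len(ncol(p)), function(i) matrix(p[, i], 64, 64))
}

# normalize a 2D slice with whole-volume extrema and apply the storage
# precision contract (no resizing; tiles are cut at native resolution)
normalize_slice <- function(slice, vmin, vmax) {
  if (vmax > vmin) {
    s <- (slice - vmin) / (vmax - vmin)
    s[s < 0] <- 0; s[s > 1] <- 1
  } else {
    s <- slice; s[] <- 0
  }
  half_precision(s)
}

# Collect tiles (and optionally matching ground-truth tiles) for one view.
# Applies the axial stretch to volume, mask and region when the view needs it.
collect_view_tiles <- function(volume, region, view, mask = NULL,
                               stride = 32L, size = 64L, frac_min = 1 / 3,
                               abs_min = 1000) {
  dims <- dim(volume$data)
  vmin <- min(volume$data); vmax <- max(volume$data)
  rmask <- region_mask(region, spacing = volume$spacing, dim = dims)
  stretch <- 1
  vol_use <- volume; rmask_use <- rmask; mask_use <- mask
  if (view != "axial" && dims[1] < size) {
    sv <- stretch_axial(volume, size)
    vol_use <- sv$object; stretch <- sv$factor
    rmask_use <- stretch_axial(rmask, size)$object
    if (!is.null(mask)) mask_use <- stretch_axial(mask, size)$object
  }
  n <- dim(vol_use$data)[view_axis(view)]
  tiles <- list(); truths <- list()
  for (k in seq_len(n)) {
    cross <- slice_at(rmask_use$data, view, k)
    if (!any(cross > 0)) next
    img <- normalize_slice(slice_at(vol_use$data, view, k), vmin, vmax)
    tl <- sample_tiles(img, cross, view, k, stride = stride, size = size,
                       frac_min = frac_min, abs_min = abs_min,
                       stretch = stretch)
    if (length(tl) == 0L) next
    tiles <- c(tiles, tl)
    if (!is.null(mask)) {
      msl <- slice_at(mask_use$data, view, k)
      truths <- c(truths, lapply(tl, function(t)
        msl[t$row:(t$row + size - 1L), t$col:(t$col + size - 1L)]))
    }
  }
  list(tiles = tiles, truths = if (is.null(mask)) NULL else truths,
       stretch = stretch)
}

#' Predict a per-view 3D segmentation mask
#'
#' Samples 64 x 64 tiles around the positive region on every slice of the
#' view (stretching the axial axis when needed), predicts each tile with the
#' U-Net, reinserts predictions into a zero-initialized 3D array of the
#' volume's size (overlaps fused), and binarizes the fused probabilities.
#' An empty region yields an empty mask regardless of the model.
#'
#' @param model A trained `rpe_unet` for this view.
#' @param volume An [image_volume].
#' @param region A `positive_region` from [build_region()].
#' @param view One of the three anatomical views.
#' @param threshold Binarization threshold on fused probabilities.
#' @param stride,size,frac_min,abs_min Tile sampling parameters (see
#'   [sample_tiles()]).
#' @param fusion Overlap fusion rule, `"mean"` or `"max"`.
#' @return A [binary_mask] with attribute `n_tiles`.
#' @export
predict_view_mask <- function(model, volume, region, view = plane_views(),
                              threshold = 0.5, stride = 32L, size = 64L,
                              frac_min = 1 / 3, abs_min = 1000,
                              fusion = "mean") {
  view <- match.arg(view)
  stopifnot(inherits(model, "rpe_unet"), inherits(volume, "image_volume"))
  if (!is.null(model$view) && !identical(model$view, view))
    abort(sprintf("model was trained for the %s view, not %s.", model$view, view))
  dims <- dim(volume$data)
  cv <- collect_view_tiles(volume, region, view, mask = NULL, stride = stride,
                           size = size, frac_min = frac_min, abs_min = abs_min)
  if (length(cv$tiles) == 0L) {
    out <- binary_mask(array(0L, dims), volume$spacing)
    attr(out, "n_tiles") <- 0L
    return(out)
  }
  preds <- predict_tiles(model, cv$tiles)
  score <- reassemble(cv$tiles, preds, dims, fusion = fusion)
  out <- binary_mask(array(as.integer(score >= threshold), dims), volume$spacing)
  attr(out, "n_tiles") <- length(cv$tiles)
  out
}

#' 2.5-dimensional majority vote over the three per-view masks
#'
#' A voxel of the fused mask is positive iff it is positive in at least two
#' of the coronal-, sagittal- and axial-derived masks.
#'
#' @param mask_cor,mask_sag,mask_ax Congruent [binary_mask] objects.
#' @return The fused [binary_mask].
#' @export
majority_vote <- function(mask_cor, mask_sag, mask_ax) {
  stopifnot(inherits(mask_cor, "binary_mask"), inherits(mask_sag, "binary_mask"),
            inherits(mask_ax, "binary_mask"))
  check_congruent(mask_cor, mask_sag)
  check_congruent(mask_cor, mask_ax)
  votes <- mask_cor$data + mask_sag$data + mask_ax$data
  binary_mask(array(as.integer(votes >= 2L), dim(votes)), mask_cor$spacing)
}
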