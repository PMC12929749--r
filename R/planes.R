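#' Extract all 2D slices of a volume along one anatomical view
#'
#' With data indexed `[z, y, x]`, axial slice `k` is `data[k, , ]` (a y-by-x
#' matrix), coronal slice `k` is `data[, k, ]` (z-by-x) and sagittal slice `k`
#' is `data[, , k]` (z-by-y). Slices are returned in ascending index order.
#'
#' @param volume An [image_volume] (or a [binary_mask], whose grid is sliced
#'   the same way).
#' @param view One of `"axial"`, `"coronal"`, `"sagittal"`.
#' @return List of 2D matrices, one per slice index.
#' @export
#' @examples
#' vol <- image_volume(array(seq_len(4 * 6 * 8), c(4, 6, 8)), c(4.8, .5, .5))
#' length(extract_slices(vol, "coronal"))  # 6
extract_slices <- function(volume, view = plane_views()) {
  view <- match.arg(view)
  data <- if (inherits(volume, "image_volume") || inherits(volume, "binary_mask"))
    volume$data else volume
  axis <- view_axis(view)
  n <- dim(data)[axis]
  lapply(seq_len(n), function(k) slice_at(data, view, k))
}

slice_at <- function(data, view, k) {
  switch(view,
         axial    = data[k, , , drop = TRUE],
         coronal  = data[, k, , drop = TRUE],
         sagittal = data[, , k, drop = TRUE])
}

#' Round values to their nearest half-precision representation
#'
#' Preprocessed slices and tiles are stored under a reduced-precision
#' contract: every value is representable as an IEEE-754 half-precision
#' number. Computation elsewhere stays in full precision.
#'
#' @param x Numeric vector, matrix or array.
#' @return Object of the same shape with each value rounded to the nearest
#'   float16-representable number.
#' @export
#' @examples
#' half_precision(1/3)
half_precision <- function(x) {
  out <- cpp_round_half(as.numeric(x))
  if (!is.null(dim(x))) dim(out) <- dim(x)
  out
}

#' Resize a 2D matrix
#'
#' Bilinear interpolation for intensities; nearest neighbour for masks so they
#' stay binary.
#'
#' @param x Numeric matrix.
#' @param nrow,ncol Target dimensions.
#' @param method `"bilinear"` or `"nearest"`.
#' @return Resized matrix.
#' @export
resize_2d <- function(x, nrow, ncol, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  if (nrow(x) == nrow && ncol(x) == ncol) return(x)
  filt <- if (method == "bilinear") "bilinear" else "none"
  out <- EBImage::resize(x, w = nrow, h = ncol, filter = filt)
  matrix(as.numeric(out), nrow, ncol)
}

#' Preprocess a slice into a classifier input
#'
#' Bilinear resize to `size` x `size`, then an affine map
#' `(v - volume_min) / (volume_max - volume_min)` into `[0, 1]` using the
#' whole-volume intensity extrema (not per-slice extrema, which would erase
#' the inter-slice intensity cue that distinguishes edematous slices),
#' stored at half precision. A constant volume (`max == min`) maps to all
#' zeros.
#'
#' @param slice 2D numeric matrix.
#' @param volume_min,volume_max Whole-volume intensity extrema,
#'   `volume_max >= volume_min`.
#' @param size Output side length in pixels (default 128, the classifier
#'   input size).
#' @return `size` x `size` matrix with values in `[0, 1]`.
#' @export
preprocess_slice <- function(slice, volume_min, volume_max, size = 128L) {
  stopifnot(volume_max >= volume_min)
  out <- resize_2d(slice, size, size, method = "bilinear")
  if (volume_max > volume_min) {
    out <- (out - volume_min) / (volume_max - volume_min)
    out[out < 0] <- 0
    out[out > 1] <- 1
  } else {
    out[] <- 0
  }
  half_precision(out)
}

#' Ground-truth slice label along a view
#'
#' A slice is positive (1) iff the mask's 2D sub-grid at that view and index
#' contains at least one positive voxel.
#'
#' @param mask A [binary_mask].
#' @param view One of `"axial"`, `"coronal"`, `"sagittal"`.
#' @param index Slice index (1-based); must be within range.
#' @return 0 or 1.
#' @export
slice_label <- function(mask, view = plane_views(), index) {
  view <- match.arg(view)
  stopifnot(inherits(mask, "binary_mask"))
  n <- dim(mask$data)[view_axis(view)]
  if (index < 1L || index > n) abort("slice index out of range.")
  as.integer(any(slice_at(mask$data, view, index) > 0))
}

#' Ground-truth labels for every slice of a view
#'
#' @inheritParams slice_label
#' @return Integer vector of 0/1 labels, one per slice.
#' @export
slice_labels <- function(mask, view = plane_views()) {
  view <- match.arg(view)
  stopifnot(inherits(mask, "binary_mask"))
  as.integer(apply(mask$data, view_axis(view), max) > 0)
}
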