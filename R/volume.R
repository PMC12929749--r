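#' Construct a 3D image volume
#'
#' The unit of patient data: a 3D scalar grid indexed `[z, y, x]` (axial slice
#' index, anterior-posterior, left-right) with strictly positive per-axis voxel
#' spacing in millimetres. Neck MRI of the kind this package targets is
#' strongly anisotropic: roughly 0.5 mm in plane and ~4.8 mm between axial
#' slices.
#'
#' @param data Numeric 3D array indexed `[z, y, x]`; all values finite.
#' @param spacing Numeric length-3 vector `c(dz, dy, dx)` in mm, all > 0.
#' @param id Identifier string.
#' @return An object of class `image_volume` with fields `id`, `data`,
#'   `spacing`.
#' @export
#' @examples
#' vol <- image_volume(array(rnorm(8 * 16 * 16), c(8, 16, 16)),
#'                     spacing = c(4.8, 0.5, 0.5), id = "example")
#' dim(vol$data)
image_volume <- function(data, spacing, id = "volume") {
  if (!is.array(data) || length(dim(data)) != 3L)
    abort("`data` must be a 3D array indexed [z, y, x].")
  if (any(dim(data) < 1L)) abort("all three dimensions must be >= 1.")
  if (!all(is.finite(data))) abort("intensities must be finite.")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    abort("`spacing` must be three strictly positive values (dz, dy, dx) in mm.")
  structure(list(id = as.character(id), data = data, spacing = spacing),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_volume '%s'>  %d x %d x %d voxels [z,y,x], spacing %.3f x %.3f x %.3f mm\n",
              x$id, d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Construct a binary 3D mask
#'
#' A `{0,1}` grid congruent in shape to its image volume, with the voxel
#' spacing inherited from the volume; used for both ground-truth and predicted
#' segmentations.
#'
#' @param data 3D array with values exactly 0 or 1.
#' @param spacing Numeric `c(dz, dy, dx)` in mm.
#' @return An object of class `binary_mask`.
#' @export
#' @examples
#' m <- array(0L, c(4, 8, 8)); m[2, 3:5, 4] <- 1L
#' mask <- binary_mask(m, spacing = c(4.8, 0.5, 0.5))
binary_mask <- function(data, spacing) {
  if (!is.array(data) || length(dim(data)) != 3L)
    abort("`data` must be a 3D array indexed [z, y, x].")
  if (!all(data %in% c(0, 1)))
    abort("mask values must be exactly 0 or 1.")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    abort("`spacing` must be three strictly positive values (dz, dy, dx) in mm.")
  storage.mode(data) <- "integer"
  structure(list(data = data, spacing = spacing), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<binary_mask>  %d x %d x %d voxels, %d positive (%.4f%%)\n",
              d[1], d[2], d[3], sum(x$data), 100 * mean(x$data)))
  invisible(x)
}

check_congruent <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data)))
    abort("geometry error: shapes are not congruent.")
  if (!isTRUE(all.equal(a$spacing, b$spacing, tolerance = 1e-8)))
    abort("geometry error: voxel spacings differ.")
  invisible(TRUE)
}

#' Lesion volume of a binary mask in cubic millimetres
#'
#' Multiplies the positive-voxel count by the voxel volume
#' `dz * dy * dx`; the physical quantity that the whole pipeline ultimately
#' estimates.
#'
#' @param mask A [binary_mask].
#' @return A list with `voxel_count` and `mm3`, class `volume_estimate`.
#' @export
#' @examples
#' m <- array(0L, c(4, 8, 8)); m[2, 1:5, 4] <- 1L
#' mask_volume_mm3(binary_mask(m, c(4.8, 0.5, 0.5)))
mask_volume_mm3 <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  n <- sum(mask$data)
  structure(list(voxel_count = as.integer(n), mm3 = n * prod(mask$spacing)),
            class = "volume_estimate")
}

#' @export
print.volume_estimate <- function(x, ...) {
  cat(sprintf("<volume_estimate>  %d voxels = %.2f mm^3\n", x$voxel_count, x$mm3))
  invisible(x)
}

#' Dice similarity coefficient between two binary masks
#'
#' `2 |X intersect Y| / (|X| + |Y|)` where `|X|` and `|Y|` count positive
#' voxels in the predicted and ground-truth masks. Only lesion-positive
#' ground truth is admissible: an entirely empty `truth` makes the
#' denominator convention-dependent and raises an error.
#'
#' @param pred,truth Congruent [binary_mask] objects; `truth` must contain at
#'   least one positive voxel.
#' @return Dice score in `[0, 1]`.
#' @export
#' @examples
#' a <- array(0L, c(2, 4, 4)); a[1, 1:2, 1:2] <- 1L
#' b <- array(0L, c(2, 4, 4)); b[1, 1:3, 1:2] <- 1L
#' dice_coefficient(binary_mask(a, c(1, 1, 1)), binary_mask(b, c(1, 1, 1)))
dice_coefficient <- function(pred, truth) {
  stopifnot(inherits(pred, "binary_mask"), inherits(truth, "binary_mask"))
  check_congruent(pred, truth)
  ny <- sum(truth$data)
  if (ny == 0L)
    abort("undefined denominator: ground-truth mask has no positive voxels.")
  nx <- sum(pred$data)
  ni <- sum(pred$data & truth$data)
  2 * ni / (nx + ny)
}
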