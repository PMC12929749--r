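#' Build the 3D positive region from per-view slice labels
#'
#' The coarse localization stage: a voxel `(z, y, x)` belongs to the region
#' iff its axial slice `z`, coronal slice `y` and sagittal slice `x` were all
#' predicted positive. The region is therefore the set product of the three
#' positive index sets; non-contiguous label runs are kept as-is rather than
#' bridged into one contiguous box.
#'
#' @param axial_labels,coronal_labels,sagittal_labels Binary 0/1 vectors whose
#'   lengths equal the volume's z, y and x dimensions.
#' @return An object of class `positive_region` with fields `z`, `y`, `x`
#'   (1-based positive index sets), `dim`, `voxel_count`, and `bbox` (tight
#'   per-axis min/max, NULL when empty).
#' @export
#' @examples
#' r <- build_region(c(0, 1, 0), c(1, 0, 1), c(0, 1, 1))
#' r$voxel_count  # 1 * 2 * 2 = 4
build_region <- function(axial_labels, coronal_labels, sagittal_labels) {
  chk <- function(v, nm) {
    if (!all(v %in% c(0, 1))) abort(paste0("`", nm, "` must be binary 0/1."))
    as.integer(v)
  }
  az <- chk(axial_labels, "axial_labels")
  co <- chk(coronal_labels, "coronal_labels")
  sa <- chk(sagittal_labels, "sagittal_labels")
  z <- which(az == 1L); y <- which(co == 1L); x <- which(sa == 1L)
  empty <- length(z) == 0L || length(y) == 0L || length(x) == 0L
  structure(list(
    z = z, y = y, x = x,
    dim = c(length(az), length(co), length(sa)),
    voxel_count = length(z) * length(y) * length(x),
    bbox = if (empty) NULL else
      list(z = range(z), y = range(y), x = range(x))
  ), class = "positive_region")
}

#' @export
print.positive_region <- function(x, ...) {
  cat(sprintf("<positive_region>  |Z|=%d |Y|=%d |X|=%d  (%d voxels of %d x %d x %d)\n",
              length(x$z), length(x$y), length(x$x), x$voxel_count,
              x$dim[1], x$dim[2], x$dim[3]))
  invisible(x)
}

#' Test voxel membership in a positive region
#'
#' @param region A [build_region()] result.
#' @param z,y,x Voxel indices (1-based).
#' @return Logical.
#' @export
region_contains <- function(region, z, y, x) {
  (z %in% region$z) & (y %in% region$y) & (x %in% region$x)
}

#' Materialize a positive region as a binary mask
#'
#' Needed, among other things, for the diagnostic Dice between the coarse
#' bounding region and the ground truth.
#'
#' @param region A `positive_region`.
#' @param spacing Voxel spacing `c(dz, dy, dx)` in mm for the returned mask.
#' @param dim Target grid dimensions; defaults to the label lengths the region
#'   was built from.
#' @return A [binary_mask] whose positive count equals `region$voxel_count`.
#' @export
region_mask <- function(region, spacing = c(1, 1, 1), dim = region$dim) {
  stopifnot(inherits(region, "positive_region"))
  if (any(region$dim > dim))
    abort("region indices out of range for the requested dimensions.")
  m <- array(0L, dim)
  if (region$voxel_count > 0L) m[region$z, region$y, region$x] <- 1L
  binary_mask(m, spacing)
}

#' One-row summary of a positive region
#'
#' @param region A `positive_region`.
#' @param id Optional identifier column.
#' @return A tibble with index-set sizes, voxel count and the tight bounding
#'   box extents.
#' @export
region_summary <- function(region, id = NA_character_) {
  bb <- region$bbox
  tibble::tibble(
    id = id,
    n_z = length(region$z), n_y = length(region$y), n_x = length(region$x),
    voxel_count = region$voxel_count,
    z_min = if (is.null(bb)) NA_integer_ else bb$z[1],
    z_max = if (is.null(bb)) NA_integer_ else bb$z[2],
    y_min = if (is.null(bb)) NA_integer_ else bb$y[1],
    y_max = if (is.null(bb)) NA_integer_ else bb$y[2],
    x_min = if (is.null(bb)) NA_integer_ else bb$x[1],
    x_max = if (is.null(bb)) NA_integer_ else bb$x[2])
}
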