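#' Read and write volumes and masks as NIfTI-1
#'
#' Volumes and masks are exchanged as NIfTI-1 files (`.nii` / `.nii.gz`).
#' On disk NIfTI stores the grid as `[x, y, z]` with per-axis spacings in the
#' same order; these functions transpose to and from the package's `[z, y, x]`
#' convention, so a round trip preserves grid values exactly and spacing to
#' float precision. Masks are written as unsigned 8-bit with values `{0, 1}`
#' and are validated on read.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @param id Identifier for the returned volume; defaults to the file stem.
#' @return `read_volume()` an [image_volume]; `read_mask()` a [binary_mask];
#'   the writers return `path` invisibly.
#' @name nifti_io
#' @examples
#' vol <- image_volume(array(rnorm(8 * 16 * 16), c(8, 16, 16)), c(4.8, .5, .5))
#' f <- tempfile(fileext = ".nii.gz")
#' write_volume(vol, f)
#' identical(read_volume(f)$data, vol$data)
NULL

nifti_spacing <- function(img) {
  pd <- RNifti::pixdim(img)
  if (length(pd) < 3L || any(!is.finite(pd[1:3])) || any(pd[1:3] <= 0))
    abort("format error: NIfTI file has no usable voxel spacing.")
  pd[1:3]
}

#' @rdname nifti_io
#' @export
read_volume <- function(path, id = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) arr <- arr[, , , 1L]
  if (length(dim(arr)) != 3L)
    abort("format error: expected a 3D NIfTI image.")
  sp <- nifti_spacing(img)  # (dx, dy, dz)
  if (is.null(id)) id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  image_volume(aperm(arr, c(3, 2, 1)), spacing = rev(sp), id = id)
}

#' @rdname nifti_io
#' @param volume An [image_volume] to write.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "image_volume"))
  arr <- aperm(volume$data, c(3, 2, 1))  # back to (x, y, z)
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rev(volume$spacing)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' @rdname nifti_io
#' @export
read_mask <- function(path) {
  vol <- read_volume(path)
  binary_mask(vol$data, spacing = vol$spacing)
}

#' @rdname nifti_io
#' @param mask A [binary_mask] to write.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  arr <- aperm(mask$data, c(3, 2, 1))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rev(mask$spacing)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}
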