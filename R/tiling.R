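# z-axis resampling and 64x64 tile sampling around the positive region.

# continuous source coordinate of stretched index k (1-based, center aligned)
z_map_nearest <- function(k, n_src, n_dst) {
  pmin(pmax(floor((k - 0.5) * n_src / n_dst + 1), 1L), n_src)
}

stretch_z_data <- function(data, target, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  nz <- dim(data)[1]
  k <- seq_len(target)
  if (method == "nearest") {
    out <- data[z_map_nearest(k, nz, target), , , drop = FALSE]
  } else {
    p <- (k - 0.5) * nz / target + 0.5
    i0 <- pmin(pmax(floor(p), 1), nz)
    i1 <- pmin(i0 + 1, nz)
    w <- pmin(pmax(p - i0, 0), 1)
    out <- (1 - w) * data[i0, , , drop = FALSE] + w * data[i1, , , drop = FALSE]
  }
  out
}

#' Stretch a volume or mask along the axial axis to a minimum slice count
#'
#' Coronal and sagittal tile sampling needs at least 64 rows along z; volumes
#' with fewer axial slices are resampled along z to exactly `min_len`
#' (bilinear for intensities, nearest neighbour for masks so they stay
#' binary). In-plane axes are untouched. Volumes already at least `min_len`
#' slices tall are returned unchanged with factor 1.
#'
#' @param x An [image_volume] or [binary_mask].
#' @param min_len Minimum axial length (default 64, the tile side).
#' @return List with `object` (same class as `x`), `factor`
#'   (`min_len / n_axial`, 1 when no stretch applied) and `original_length`.
#' @export
#' @examples
#' v <- image_volume(array(rnorm(32 * 64 * 64), c(32, 64, 64)), c(4.8, .5, .5))
#' s <- stretch_axial(v)
#' dim(s$object$data)[1]  # 64
#' s$factor               # 2
stretch_axial <- function(x, min_len = 64L) {
  is_mask <- inherits(x, "binary_mask")
  if (!is_mask && !inherits(x, "image_volume"))
    abort("`x` must be an image_volume or binary_mask.")
  nz <- dim(x$data)[1]
  if (nz >= min_len)
    return(list(object = x, factor = 1, original_length = nz))
  method <- if (is_mask) "nearest" else "bilinear"
  data <- stretch_z_data(x$data, min_len, method)
  obj <- if (is_mask) binary_mask(data, x$spacing) else {
    v <- x; v$data <- data; v
  }
  list(object = obj, factor = min_len / nz, original_length = nz)
}

# inverse of the nearest-neighbour stretch for 3D arrays (score maps, masks)
unstretch_z_data <- function(data, original_length) {
  n_dst <- dim(data)[1]
  if (n_dst == original_length) return(data)
  i <- seq_len(original_length)
  k <- pmin(pmax(floor((i - 0.5) * n_dst / original_length + 1), 1L), n_dst)
  data[k, , , drop = FALSE]
}

#' Tile offset lattice along one axis
#'
#' Offsets are multiples of the stride starting at 1; when the axis length is
#' not stride-aligned a final offset clamped to the edge is appended so the
#' whole axis is coverable.
#'
#' @param len Axis length in pixels (must be >= `size`).
#' @param size Tile side (default 64).
#' @param stride Lattice stride (default 32).
#' @return Integer vector of 1-based offsets.
#' @export
tile_lattice <- function(len, size = 64L, stride = 32L) {
  len <- as.integer(len); size <- as.integer(size); stride <- as.integer(stride)
  if (len < size) abort("geometry error: axis shorter than the tile size.")
  offs <- seq.int(1L, len - size + 1L, by = stride)
  if (offs[length(offs)] != len - size + 1L) offs <- c(offs, len - size + 1L)
  as.integer(offs)
}

#' Sample 64 x 64 tiles around the positive region on one slice
#'
#' Candidate squares live on the stride lattice; a square is kept iff the
#' number of region pixels it contains is at least `frac_min` times the
#' region's cross-sectional pixel count on the whole slice, or at least
#' `abs_min` pixels. The absolute criterion was calibrated to full-size
#' (288-640 px) slices; at other scales it should be multiplied by
#' `(in_plane / 512)^2` (the experiment driver does this automatically).
#'
#' @param slice 2D numeric matrix (already normalized) to cut pixels from.
#' @param region_cross Binary matrix congruent to `slice`: the region's
#'   cross-section on this slice.
#' @param view,index Provenance: the anatomical view and slice index.
#' @param stride,size Lattice stride and tile side.
#' @param frac_min Fractional criterion (default 1/3).
#' @param abs_min Absolute pixel criterion (default 1000, the full-scale
#'   value).
#' @param stretch Stretch factor recorded in each tile's provenance.
#' @return List of tiles; each tile is a list with `pixels` (size x size
#'   matrix), `view`, `index`, `row`, `col`, `stretch`.
#' @export
sample_tiles <- function(slice, region_cross, view, index,
                         stride = 32L, size = 64L, frac_min = 1 / 3,
                         abs_min = 1000, stretch = 1) {
  if (!identical(dim(slice), dim(region_cross)))
    abort("geometry error: slice and region cross-section differ in shape.")
  index <- as.integer(index)
  size <- as.integer(size)
  total <- sum(region_cross)
  if (total == 0) return(list())
  rows <- tile_lattice(nrow(slice), size, stride)
  cols <- tile_lattice(ncol(slice), size, stride)
  out <- list()
  for (r0 in rows) for (c0 in cols) {
    cnt <- sum(region_cross[r0:(r0 + size - 1L), c0:(c0 + size - 1L)])
    if (cnt >= frac_min * total || cnt >= abs_min) {
      out[[length(out) + 1L]] <- list(
        pixels = slice[r0:(r0 + size - 1L), c0:(c0 + size - 1L)],
        view = view, index = index, row = r0, col = c0, stretch = stretch)
    }
  }
  out
}

#' Tile manifest as a tibble
#'
#' @param tiles List of tiles from [sample_tiles()].
#' @return Tibble with one row per tile (provenance only, no pixels).
#' @export
tile_manifest <- function(tiles) {
  tibble::tibble(
    view = vapply(tiles, `[[`, character(1), "view"),
    index = as.integer(vapply(tiles, function(t) as.numeric(t$index), numeric(1))),
    row = as.integer(vapply(tiles, function(t) as.numeric(t$row), numeric(1))),
    col = as.integer(vapply(tiles, function(t) as.numeric(t$col), numeric(1))),
    stretch = vapply(tiles, `[[`, numeric(1), "stretch"))
}

# place one size x size block addressed by tile provenance into a 3D array
tile_block_indices <- function(tile, size = 64L) {
  r <- tile$row:(tile$row + size - 1L)
  c <- tile$col:(tile$col + size - 1L)
  switch(tile$view,
         axial    = list(z = tile$index, y = r, x = c),
         coronal  = list(z = r, y = tile$index, x = c),
         sagittal = list(z = r, y = c, x = tile$index))
}

#' Reassemble per-tile predictions into a 3D score map
#'
#' Initializes a zero array of the (possibly axially stretched) volume shape,
#' inserts every tile's 64 x 64 prediction at its recorded location, averages
#' where tiles overlap, and finally applies the inverse axial stretch.
#' Voxels covered by no tile stay 0 ("no edema").
#'
#' @param tiles List of tiles (provenance is read from them).
#' @param predictions List of 64 x 64 prediction matrices in `[0, 1]`,
#'   parallel to `tiles`.
#' @param dim Target (original volume) dimensions `c(nz, ny, nx)`.
#' @param fusion `"mean"` (average overlapping predictions) or `"max"`.
#' @return 3D numeric score array of dimensions `dim`.
#' @export
reassemble <- function(tiles, predictions, dim, fusion = c("mean", "max")) {
  fusion <- match.arg(fusion)
  stopifnot(length(tiles) == length(predictions))
  stretch <- if (length(tiles)) tiles[[1L]]$stretch else 1
  acc_dim <- dim
  if (stretch > 1) acc_dim[1] <- round(dim[1] * stretch)
  acc <- array(0, acc_dim)
  cnt <- array(0L, acc_dim)
  for (i in seq_along(tiles)) {
    ix <- tile_block_indices(tiles[[i]])
    if (max(ix$z) > acc_dim[1] || max(ix$y) > acc_dim[2] || max(ix$x) > acc_dim[3])
      abort("tile provenance outside the target shape.")
    p <- predictions[[i]]
    if (fusion == "mean") {
      acc[ix$z, ix$y, ix$x] <- acc[ix$z, ix$y, ix$x] + p
    } else {
      acc[ix$z, ix$y, ix$x] <- pmax(acc[ix$z, ix$y, ix$x], p)
    }
    cnt[ix$z, ix$y, ix$x] <- cnt[ix$z, ix$y, ix$x] + 1L
  }
  if (fusion == "mean") {
    covered <- cnt > 0L
    acc[covered] <- acc[covered] / cnt[covered]
  }
  unstretch_z_data(acc, dim[1])
}
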