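#' Specification for a synthetic neck phantom
#'
#' Describes one synthetic anisotropic volume with a single retropharyngeal
#' lesion. Fields left `NULL` are sampled at generation time from the
#' distributions observed in clinical neck MRI of this kind: 26-60 axial
#' slices, slice spacing Normal(4.80, 0.228) mm clipped to [3.98, 5.96],
#' in-plane spacing Normal(0.528, 0.149) mm clipped to [0.375, 0.694], and a
#' lesion volume drawn log-uniformly from [234, 31490] mm^3 scaled by
#' `(in_plane / 512)^2` and truncated to the volume range that keeps the
#' positive-voxel fraction inside the sparsity band [0.0023%, 0.31%] for the
#' sampled grid.
#'
#' @param in_plane In-plane grid side in pixels. 128 keeps end-to-end
#'   experiments fast while preserving the extreme lesion sparsity that
#'   motivates the coarse-to-fine design; the clinical range 288-640 is
#'   selectable.
#' @param n_axial Number of axial slices, or `NULL` to sample from 26:60.
#' @param spacing `c(dz, dy, dx)` in mm, or `NULL` to sample.
#' @param lesion_volume_mm3 Target lesion volume in mm^3; `NULL` to sample as
#'   above; `0` for a lesion-free (negative) phantom.
#' @param lesion_contrast Mean lesion intensity divided by mean background
#'   intensity (> 1). The paper's modality (fat-suppressed T2) shows edema as
#'   markedly hyperintense; contrast is a free phantom parameter, not a claim
#'   about real tissue values.
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(in_plane = 128L, n_axial = NULL, spacing = NULL,
                         lesion_volume_mm3 = NULL, lesion_contrast = 3,
                         noise_sd = 0.05, seed = NULL) {
  if (in_plane < 64L) abort("`in_plane` must be at least 64 (the tile size).")
  if (lesion_contrast <= 1) abort("`lesion_contrast` must exceed 1.")
  structure(list(in_plane = as.integer(in_plane), n_axial = n_axial,
                 spacing = spacing, lesion_volume_mm3 = lesion_volume_mm3,
                 lesion_contrast = lesion_contrast, noise_sd = noise_sd,
                 seed = seed),
            class = "phantom_spec")
}

clip_norm <- function(mean, sd, lo, hi) min(max(rnorm(1, mean, sd), lo), hi)

# Threshold a scalar field so that its largest 26-connected superlevel
# component holds ~n_target voxels. Superlevel sets are nested, so the
# largest-component size is monotone in the threshold; binary search finds
# the highest threshold whose component reaches the target, and a field-
# ordered trim inside that component removes any overshoot from merges.
lesion_from_field <- function(field, n_target) {
  dims <- dim(field)
  largest <- function(thr) {
    raw <- array(as.integer(field >= thr), dims)
    lab <- cpp_label_components(raw, dims)
    array(as.integer(lab == 1L), dims)
  }
  lo <- min(field); hi <- max(field)
  for (i in 1:30) {
    mid <- (lo + hi) / 2
    if (sum(largest(mid)) >= n_target) lo <- mid else hi <- mid
  }
  comp <- largest(lo)
  n <- sum(comp)
  if (n > n_target) {
    # keep the n_target highest-field voxels of the component, then re-take
    # the largest connected piece in case the trim disconnected it
    idx <- which(comp == 1L)
    keep <- idx[order(field[idx], decreasing = TRUE)[seq_len(n_target)]]
    trimmed <- array(0L, dims); trimmed[keep] <- 1L
    lab <- cpp_label_components(trimmed, dims)
    trimmed <- array(as.integer(lab == 1L), dims)
    if (abs(sum(trimmed) - n_target) < abs(n - n_target)) comp <- trimmed
  }
  comp
}

# sparsity band for the positive-voxel fraction (percent of all voxels)
.sparsity_band <- c(0.0023, 0.31)

sample_lesion_volume <- function(in_plane, n_axial, voxvol) {
  scale <- (in_plane / 512)^2
  total <- as.numeric(in_plane)^2 * n_axial
  # clinical volume range, area-scaled, truncated to the sampled grid's
  # sparsity band (with a small guard for discretization error)
  lo <- max(234 * scale, 1.05 * .sparsity_band[1] / 100 * total * voxvol)
  hi <- min(31490 * scale, 0.95 * .sparsity_band[2] / 100 * total * voxvol)
  if (hi <= lo) return(max(lo, min(hi, 234 * scale)))
  exp(runif(1, log(lo), log(hi)))
}

#' Generate one synthetic neck phantom
#'
#' Builds a background of simple anatomic surrogates (a dark anterior airway
#' column, a vertebral column, bright fat planes, a slow intensity gradient)
#' plus Gaussian noise, and embeds one bright lesion shaped like
#' retropharyngeal edema: a thin anterior band, tall along z, wide along x,
#' thin along y. The lesion is the union of overlapping anisotropic Gaussian
#' blobs thresholded at exactly the target voxel count, with only the largest
#' 26-connected component kept (mirroring the single-continuous-area reading
#' of the ground truth).
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `phantom_case` with `volume` ([image_volume]),
#'   `mask` ([binary_mask]), the realized `spec`, `target_mm3` and achieved
#'   `lesion_mm3`.
#' @export
#' @examples
#' case <- generate_phantom(phantom_spec(in_plane = 64, seed = 7))
#' mean(case$mask$data) * 100  # positive-voxel percentage
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed_if(spec$seed, generate_phantom_impl(spec))
}

generate_phantom_impl <- function(spec) {
  P <- spec$in_plane
  nz <- if (is.null(spec$n_axial)) sample(26:60, 1) else as.integer(spec$n_axial)
  sp <- if (is.null(spec$spacing)) {
    dyx <- clip_norm(0.528, 0.149, 0.375, 0.694)
    c(clip_norm(4.80, 0.228, 3.98, 5.96), dyx, dyx)
  } else as.numeric(spec$spacing)
  voxvol <- prod(sp)
  target <- if (is.null(spec$lesion_volume_mm3))
    sample_lesion_volume(P, nz, voxvol) else spec$lesion_volume_mm3

  # --- background ------------------------------------------------------------
  zc <- seq_len(nz); yc <- seq_len(P); xc <- seq_len(P)
  vol <- array(0.28, c(nz, P, P))
  vol <- vol + 0.04 * rep(yc / P, each = nz)  # slow anterior-posterior ramp
  ygrid <- matrix(yc, P, P); xgrid <- matrix(xc, P, P, byrow = TRUE)
  wobble <- 0.02 * P * sin(2 * pi * zc / nz)
  for (k in zc) {
    airway <- ((ygrid - 0.22 * P) / (0.06 * P))^2 +
      ((xgrid - 0.5 * P - wobble[k]) / (0.10 * P))^2 <= 1
    vert <- ((ygrid - 0.45 * P) / (0.08 * P))^2 +
      ((xgrid - 0.5 * P) / (0.08 * P))^2 <= 1
    sl <- vol[k, , ]
    sl[airway] <- 0.05
    sl[vert] <- 0.15
    vol[k, , ] <- sl
  }
  fat <- abs(xgrid - 0.25 * P) < 0.02 * P | abs(xgrid - 0.75 * P) < 0.02 * P |
    abs(ygrid - 0.10 * P) < 0.015 * P
  for (k in zc) { sl <- vol[k, , ]; sl[fat] <- 0.55; vol[k, , ] <- sl }
  bg_mean <- mean(vol)

  # --- lesion ----------------------------------------------------------------
  mask <- array(0L, c(nz, P, P))
  achieved_mm3 <- 0
  if (target > 0) {
    n_target <- round(target / voxvol)
    if (n_target < 1)
      abort("target lesion volume smaller than one voxel for this grid.")
    if (n_target > 0.05 * nz * P^2)
      abort("target lesion volume infeasible for this grid geometry.")
    extent <- runif(1, 0.4, 0.8) * nz
    z0 <- runif(1, extent / 2 + 1, nz - extent / 2)
    y0 <- (0.30 + runif(1, -0.02, 0.02)) * P
    x0 <- (0.50 + runif(1, -0.03, 0.03)) * P
    n_blob <- 3L
    centers_z <- z0 + seq(-1, 1, length.out = n_blob) * extent / 3
    field <- array(0, c(nz, P, P))
    for (j in seq_len(n_blob)) {
      sz <- extent / 4 * runif(1, 0.8, 1.2)
      sy <- P * runif(1, 0.015, 0.03)
      sx <- P * runif(1, 0.06, 0.12)
      cy <- y0 + runif(1, -0.02, 0.02) * P
      cx <- x0 + runif(1, -0.02, 0.02) * P
      gz <- exp(-((zc - centers_z[j])^2) / (2 * sz^2))
      gy <- exp(-((yc - cy)^2) / (2 * sy^2))
      gx <- exp(-((xc - cx)^2) / (2 * sx^2))
      field <- field + outer(outer(gz, gy), gx)
    }
    mask <- lesion_from_field(field, n_target)
    achieved_mm3 <- sum(mask) * voxvol
    lesion_value <- spec$lesion_contrast * bg_mean
    vol[mask == 1L] <- lesion_value * (1 + runif(sum(mask), -0.05, 0.05))
  }

  vol <- vol + array(rnorm(length(vol), 0, spec$noise_sd), dim(vol))

  realized <- spec
  realized$n_axial <- nz; realized$spacing <- sp
  realized$lesion_volume_mm3 <- target
  structure(list(
    volume = image_volume(vol, sp, id = "phantom"),
    mask = binary_mask(mask, sp),
    spec = realized, target_mm3 = target, lesion_mm3 = achieved_mm3),
    class = "phantom_case")
}

#' @export
print.phantom_case <- function(x, ...) {
  d <- dim(x$volume$data)
  cat(sprintf("<phantom_case '%s'>  %d x %d x %d, lesion %.1f mm^3 (%.4f%% of voxels)\n",
              x$volume$id, d[1], d[2], d[3], x$lesion_mm3,
              100 * mean(x$mask$data)))
  invisible(x)
}

#' Generate a cohort of phantoms
#'
#' Per-case geometry and lesion volume are resampled independently from the
#' spec's distributions using sub-seeds derived from the master seed, so the
#' whole cohort is reproducible from `seed` alone.
#'
#' @param n Number of phantoms (>= 1).
#' @param base_spec A [phantom_spec()]; its `NULL` fields are resampled per
#'   case.
#' @param seed Master seed.
#' @return List of `phantom_case` objects with ids `phantom_001`, ...
#' @export
generate_cohort <- function(n, base_spec = phantom_spec(), seed = 1L) {
  stopifnot(n >= 1)
  subseeds <- withr::with_seed(as.integer(seed),
                               sample.int(.Machine$integer.max - 1L, n))
  lapply(seq_len(n), function(i) {
    sp <- base_spec; sp$seed <- subseeds[i]
    case <- generate_phantom(sp)
    case$volume$id <- sprintf("phantom_%03d", i)
    case
  })
}

#' Write a phantom cohort as paired NIfTI files plus a manifest
#'
#' Writes `<id>_img.nii.gz` and `<id>_mask.nii.gz` per case and a
#' `manifest.csv` with id, spacing, lesion volume and seed.
#'
#' @param cases List of `phantom_case` objects.
#' @param dir Output directory (created if missing).
#' @return The manifest tibble, invisibly.
#' @export
write_cohort <- function(cases, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cases, function(cs) {
    write_volume(cs$volume, file.path(dir, paste0(cs$volume$id, "_img.nii.gz")))
    write_mask(cs$mask, file.path(dir, paste0(cs$volume$id, "_mask.nii.gz")))
    tibble::tibble(id = cs$volume$id,
                   dz = cs$volume$spacing[1], dy = cs$volume$spacing[2],
                   dx = cs$volume$spacing[3],
                   n_axial = dim(cs$volume$data)[1],
                   in_plane = dim(cs$volume$data)[2],
                   lesion_mm3 = cs$lesion_mm3,
                   seed = if (is.null(cs$spec$seed)) NA_integer_ else cs$spec$seed)
  })
  manifest <- dplyr::bind_rows(rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
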