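#' Volumetric image with spatial metadata
#'
#' A `volume_grid` holds a single 3D uptake image on a fixed voxel grid: the
#' voxel array, the 4x4 voxel-to-world affine (world space is MNI-152 mm for
#' spatially normalized PET), and the voxel size derived from the affine.
#' Non-finite voxels are stored as `NA` and treated as missing by all region
#' statistics; they never leak into means.
#'
#' @param values 3D numeric array of voxel values (arbitrary activity units).
#'   Non-finite entries are converted to `NA`.
#' @param affine 4x4 invertible voxel-to-world transform. Voxel indices are
#'   0-based when mapped through the affine.
#' @return An object of class `volume_grid` with fields `values`, `affine`,
#'   `dims`, `voxel_size`.
#' @export
volume_grid <- function(values, affine = diag(4)) {
  values <- check_volume_array(values)
  affine <- check_affine(affine)
  structure(
    list(values = values, affine = affine, dims = dim(values),
         voxel_size = affine_voxel_size(affine)),
    class = "volume_grid"
  )
}

#' Volume-of-interest mask on a voxel grid
#'
#' A `voi_mask` carries per-voxel weights in `[0, 1]` on the same grid
#' geometry as a [volume_grid]. Continuous (probabilistic) weights are
#' retained, but all region statistics in this package use the binary view
#' `weights >= threshold` (default 0.5), since the standard Centiloid VOIs
#' are distributed as masks and no weighting rule is part of the method.
#'
#' @param weights 3D numeric array of weights; values are clamped to
#'   `[0, 1]` and non-finite entries become weight 0.
#' @param affine 4x4 voxel-to-world transform, as in [volume_grid].
#' @param name Region label, e.g. `"CL_cortex"` or `"whole_cerebellum"`.
#' @return An object of class `voi_mask`.
#' @export
voi_mask <- function(weights, affine = diag(4), name = "VOI") {
  weights <- check_volume_array(weights)
  weights[is.na(weights)] <- 0
  weights <- pmin(pmax(weights, 0), 1)
  if (!any(weights > 0)) {
    stop("empty VOI: mask '", name, "' has no voxel with positive weight",
         call. = FALSE)
  }
  affine <- check_affine(affine)
  structure(
    list(weights = weights, affine = affine, dims = dim(weights),
         voxel_size = affine_voxel_size(affine), name = as.character(name)),
    class = "voi_mask"
  )
}

check_volume_array <- function(values) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("expected 3D volume", call. = FALSE)
  }
  storage.mode(values) <- "double"
  values[!is.finite(values)] <- NA_real_
  values
}

check_affine <- function(affine) {
  affine <- unclass(affine)
  attributes(affine) <- list(dim = dim(affine))
  if (!is.matrix(affine) || !all(dim(affine) == c(4L, 4L))) {
    stop("affine must be a 4x4 matrix", call. = FALSE)
  }
  storage.mode(affine) <- "double"
  if (abs(det(affine)) < .Machine$double.eps) {
    stop("affine is not invertible", call. = FALSE)
  }
  affine
}

affine_voxel_size <- function(affine) {
  sqrt(colSums(affine[1:3, 1:3, drop = FALSE]^2))
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> %s voxels, voxel size %s mm, %d missing\n",
              paste(x$dims, collapse = "x"),
              paste(signif(x$voxel_size, 4), collapse = "x"),
              sum(is.na(x$values))))
  invisible(x)
}

#' @export
print.voi_mask <- function(x, ...) {
  cat(sprintf("<voi_mask '%s'> %s voxels, %d in binary view (>= 0.5)\n",
              x$name, paste(x$dims, collapse = "x"),
              sum(x$weights >= 0.5)))
  invisible(x)
}

#' Read a 3D NIfTI-1 volume
#'
#' Reads a single-frame 3D NIfTI-1 image (`.nii` or `.nii.gz`). The header
#' affine is authoritative (sform preferred, qform fallback, as NIfTI
#' prescribes); non-finite voxels are flagged missing. 4D inputs are
#' rejected: dynamic data must be pre-averaged into a static frame before
#' quantification.
#'
#' @param path Path to a NIfTI-1 file.
#' @return A [volume_grid].
#' @export
read_volume <- function(path) {
  img <- read_nifti_3d(path)
  volume_grid(as_plain_array(img), affine = nifti_affine(img))
}

#' Read a VOI mask from a NIfTI-1 volume
#'
#' Reads a mask image and interprets its values as per-voxel weights.
#' Values are clamped to `[0, 1]`; masks encoded with a non-unit maximum
#' (e.g. 0/255 label images) are rescaled by their maximum before clamping.
#' The continuous weights are retained; region statistics use the binary
#' view `weights >= threshold`.
#'
#' @param path Path to a NIfTI-1 file.
#' @param threshold Weight threshold in `[0, 1]` defining the binary view
#'   (default 0.5). Stored on the mask as attribute `threshold` and used as
#'   the default by [region_mean()].
#' @param name Region label; defaults to the file name.
#' @return A [voi_mask].
#' @export
read_mask <- function(path, threshold = 0.5,
                      name = sub("\\.nii(\\.gz)?$", "", basename(path))) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold >= 0, threshold <= 1)
  img <- read_nifti_3d(path)
  w <- as_plain_array(img)
  w[!is.finite(w)] <- 0
  top <- max(w)
  if (top <= 0) stop("empty VOI: mask '", name, "' is all zero", call. = FALSE)
  if (top > 1) w <- w / top
  m <- voi_mask(w, affine = nifti_affine(img), name = name)
  attr(m, "threshold") <- threshold
  m
}

read_nifti_3d <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- img[, , , 1, drop = TRUE]
  } else if (length(d) != 3L) {
    stop("expected 3D volume, got ", length(d), "D in ", path,
         " (pre-average dynamic frames before quantification)", call. = FALSE)
  }
  img
}

nifti_affine <- function(img) {
  aff <- RNifti::xform(img)
  structure(unclass(aff)[1:4, 1:4], dim = c(4L, 4L))
}

as_plain_array <- function(img) {
  array(as.numeric(img), dim = dim(img))
}

#' Write a volume or mask as NIfTI-1
#'
#' Voxel values are written as float64 so that a write/read round-trip is
#' bit-compatible; missing voxels are written as NaN. The affine is stored
#' in the sform (code 2, aligned to a template).
#'
#' @param x A [volume_grid] or [voi_mask].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  if (inherits(x, "voi_mask")) {
    values <- x$weights
  } else if (inherits(x, "volume_grid")) {
    values <- x$values
    values[is.na(values)] <- NaN
  } else {
    stop("x must be a volume_grid or voi_mask", call. = FALSE)
  }
  img <- RNifti::asNifti(values, pixdim = x$voxel_size)
  img <- RNifti::`sform<-`(img, structure(x$affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' @rdname write_volume
#' @export
write_mask <- write_volume

#' Check that two objects live on the same voxel grid
#'
#' Region statistics require the image and mask to share one grid: this
#' package never resamples (silent interpolation would change SUVR), so a
#' grid mismatch is a hard error upstream. The check is a pure predicate:
#' dimensions must match exactly and affines elementwise within
#' `affine_tol`.
#'
#' @param a,b [volume_grid] or [voi_mask] objects.
#' @param affine_tol Absolute elementwise tolerance on the affines
#'   (default 1e-4, i.e. a tenth of a micron on typical MNI grids).
#' @return `TRUE` or `FALSE`.
#' @export
check_same_grid <- function(a, b, affine_tol = 1e-4) {
  stopifnot(inherits(a, c("volume_grid", "voi_mask")),
            inherits(b, c("volume_grid", "voi_mask")))
  identical(unname(a$dims), unname(b$dims)) &&
    max(abs(a$affine - b$affine)) <= affine_tol
}
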