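#' Region statistics over a masked volume
#'
#' Computes mean and SD of voxel values inside the binary view of a VOI mask
#' (`weights >= threshold`). Missing voxels (non-finite in the source image)
#' are excluded from the statistics — not zero-filled, which would bias SUVR
#' downward — and counted in `missing_excluded`.
#'
#' @param volume A [volume_grid].
#' @param mask A [voi_mask] on the same grid (checked with
#'   [check_same_grid()]; mismatch is an error, never a resample).
#' @param threshold Binary-view weight threshold; defaults to the threshold
#'   the mask was read with, or 0.5.
#' @return A one-row tibble with columns `region`, `voxel_count`, `mean`,
#'   `sd`, `missing_excluded`. `sd` is the sample SD (n-1 denominator; 0 for
#'   a single voxel).
#' @export
region_mean <- function(volume, mask, threshold = NULL) {
  stopifnot(inherits(volume, "volume_grid"), inherits(mask, "voi_mask"))
  if (is.null(threshold)) threshold <- attr(mask, "threshold") %||% 0.5
  if (!check_same_grid(volume, mask)) {
    stop("grid mismatch between volume and mask '", mask$name,
         "': dims or affine differ (this package never resamples)",
         call. = FALSE)
  }
  sel <- mask$weights >= threshold
  if (!any(sel)) {
    stop("empty VOI: no voxel of '", mask$name, "' reaches weight ",
         threshold, call. = FALSE)
  }
  v <- volume$values[sel]
  miss <- sum(is.na(v))
  v <- v[!is.na(v)]
  if (length(v) == 0L) {
    stop("all in-mask voxels of '", mask$name, "' are missing", call. = FALSE)
  }
  tibble::tibble(
    region = mask$name,
    voxel_count = length(v),
    mean = mean(v),
    sd = if (length(v) > 1L) stats::sd(v) else 0,
    missing_excluded = miss
  )
}

#' Compute SUVR for one subject and tracer
#'
#' SUVR (standardized uptake value ratio) is the ratio of the mean uptake in
#' the cortical target VOI to the mean uptake in the reference VOI — here, in
#' the standard Centiloid configuration, the whole cerebellum. The ratio of
#' region means is used (not a mean of voxelwise ratios); for a fixed
#' reference mean the two are equivalent, and ratio-of-means is the
#' convention adopted throughout this package. SUVR is dimensionless and
#' invariant under global intensity scaling, so no dose or weight
#' normalization is applied.
#'
#' @param volume A [volume_grid] of the spatially normalized PET image.
#' @param cortex Target [voi_mask] (standard CL cortical VOI).
#' @param reference Reference [voi_mask] (whole cerebellum).
#' @param subject_id Opaque subject label.
#' @param tracer Tracer label, e.g. `"PiB"` or `"FBB"`.
#' @return A one-row tibble (`subject_id`, `tracer`, `target_mean`,
#'   `reference_mean`, `suvr`) — the per-subject record the calibration
#'   functions consume.
#' @export
compute_suvr <- function(volume, cortex, reference,
                         subject_id = "subject", tracer = "FBB") {
  target <- region_mean(volume, cortex)
  ref <- region_mean(volume, reference)
  if (ref$mean <= 0) {
    stop("invalid reference region: mean uptake in '", reference$name,
         "' is not positive", call. = FALSE)
  }
  tibble::tibble(
    subject_id = as.character(subject_id),
    tracer = as.character(tracer),
    target_mean = target$mean,
    reference_mean = ref$mean,
    suvr = target$mean / ref$mean
  )
}
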