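#' Generate a three-region uptake phantom
#'
#' Builds a rectangular digital phantom with three non-overlapping regions —
#' a cortical shell in the upper part of the volume, a solid cerebellar
#' block in the lower part, and background elsewhere — with prescribed mean
#' uptake per region plus additive Gaussian voxel noise. The returned masks
#' mark the exact generating regions, so ground-truth SUVR is known by
#' construction: with zero noise, `compute_suvr()` returns exactly
#' `cortex_uptake / cerebellum_uptake`.
#'
#' The phantom emulates only what the quantification stage consumes (regions
#' of known mean uptake on a shared grid); it has no brain anatomy, scanner
#' resolution or partial-volume behaviour.
#'
#' @param dims Integer vector of 3 grid dimensions; at least 4 x 4 x 6.
#' @param cortex_uptake,cerebellum_uptake,background_uptake Region means in
#'   arbitrary activity units; `cerebellum_uptake` must be positive.
#' @param noise_sd SD of additive Gaussian voxel noise (same units); 0 for a
#'   noise-free phantom.
#' @param seed Integer seed; the generator is reproducible and leaves the
#'   global RNG state untouched.
#' @param voxel_size Voxel edge lengths in mm (default 2 mm isotropic, the
#'   usual grid for spatially normalized PET).
#' @return A list with elements `volume` ([volume_grid]), `cortex` and
#'   `cerebellum` ([voi_mask]s) and `spec` (the generating parameters).
#' @examples
#' ph <- generate_phantom(noise_sd = 0)
#' compute_suvr(ph$volume, ph$cortex, ph$cerebellum)
#' @export
generate_phantom <- function(dims = c(16, 16, 16),
                             cortex_uptake = 2.0,
                             cerebellum_uptake = 1.25,
                             background_uptake = 1.0,
                             noise_sd = 0,
                             seed = 1L,
                             voxel_size = c(2, 2, 2)) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L, is.numeric(noise_sd), noise_sd >= 0,
            cerebellum_uptake > 0)
  if (dims[1] < 4L || dims[2] < 4L || dims[3] < 6L) {
    stop("dims too small for the three-region phantom layout ",
         "(need at least 4 x 4 x 6)", call. = FALSE)
  }
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]

  # lower third: cerebellar block; upper third: cortical shell; 1-voxel
  # background margin on every face and a background gap between regions
  cereb <- array(FALSE, dims)
  cereb[2:(nx - 1), 2:(ny - 1), 2:(nz %/% 3)] <- TRUE
  box <- array(FALSE, dims)
  z0 <- (2L * nz) %/% 3L
  box[2:(nx - 1), 2:(ny - 1), z0:(nz - 1)] <- TRUE
  interior <- array(FALSE, dims)
  if (nx >= 6L && ny >= 6L && (nz - 2L) > (z0 + 1L)) {
    interior[3:(nx - 2), 3:(ny - 2), (z0 + 1L):(nz - 2L)] <- TRUE
  }
  cortex <- box & !interior

  values <- array(background_uptake, dims)
  values[cereb] <- cerebellum_uptake
  values[cortex] <- cortex_uptake
  if (noise_sd > 0) {
    values <- values + withr::with_seed(
      seed, array(stats::rnorm(prod(dims), 0, noise_sd), dims))
  }

  affine <- diag(c(voxel_size, 1))
  affine[1:3, 4] <- -voxel_size * dims / 2

  list(
    volume = volume_grid(values, affine),
    cortex = voi_mask(cortex * 1, affine, name = "CL_cortex"),
    cerebellum = voi_mask(cereb * 1, affine, name = "whole_cerebellum"),
    spec = list(dims = dims, cortex_uptake = cortex_uptake,
                cerebellum_uptake = cerebellum_uptake,
                background_uptake = background_uptake,
                noise_sd = noise_sd, seed = seed, voxel_size = voxel_size)
  )
}

#' Default paired-cohort group layout
#'
#' The group structure of a typical head-to-head calibration study:
#' 10 young controls, 6 elderly controls, 9 MCI, 8 mild AD and 2 FTD
#' subjects (35 in total). Group centres are set on the Centiloid scale —
#' young controls at 0 CL and mild AD at 100 CL, the anchors of the scale,
#' with elderly controls at 20, MCI at 50 and FTD at 5 CL — and mapped to
#' PiB SUVR through the inverse of the standard PiB equation. Within-group
#' spreads are generator conventions, not study estimates; the young-control
#' spread is derived from the young-normal CL variability reported for PiB
#' after removing the measurement-noise share (see the methods vignette).
#'
#' @return A tibble with columns `group`, `n`, `cl_mean`, `cl_sd`,
#'   `mean_suvr_pib`, `sd_suvr_pib`.
#' @export
default_cohort_groups <- function() {
  g <- tibble::tibble(
    group = c("young_control", "elderly_control", "mci", "ad", "ftd"),
    n = c(10L, 6L, 9L, 8L, 2L),
    cl_mean = c(0, 20, 50, 100, 5),
    cl_sd = c(2.05, 8, 12, 12, 5)
  )
  inv <- invert_map(standard_pib_map())
  g$mean_suvr_pib <- apply_map(inv, g$cl_mean)
  g$sd_suvr_pib <- g$cl_sd / standard_pib_map()$m
  g
}

#' Simulate a paired PiB/tracer SUVR cohort with known ground truth
#'
#' Draws a true PiB SUVR per subject from its group distribution, maps it
#' through a linear inter-tracer relation to the second tracer's true SUVR,
#' and adds independent Gaussian measurement noise to each tracer's observed
#' value. Both the observed pairs and the hidden truth are returned, so
#' calibration can be checked against the generating relation.
#'
#' Default noise SDs are calibrated so that the young-control observed CL
#' variability matches the reported head-to-head study conditions (SD 3.48
#' CL for PiB and 6.81 CL for the fluorinated tracer, variance ratio 1.96);
#' the derivation is in the methods vignette.
#'
#' @param groups Group layout as from [default_cohort_groups()]: columns
#'   `group`, `n`, `mean_suvr_pib`, `sd_suvr_pib`.
#' @param relation [linear_map] from `"SUVR_PiB"` to the tracer SUVR scale;
#'   default the published FBB relation slope 0.61, intercept 0.39.
#' @param pib_noise_sd,tracer_noise_sd Measurement noise SDs on the observed
#'   SUVRs (SUVR units).
#' @param seed Integer seed; reproducible, global RNG state untouched.
#' @param tracer Tracer label for the second scan.
#' @return A tibble with one row per subject: `subject_id`, `group`,
#'   `true_suvr_pib`, `true_suvr_tracer` (hidden truth) and `suvr_pib`,
#'   `suvr_tracer` (observed). The generating relation and tracer label are
#'   attached as attributes `relation` and `tracer`.
#' @examples
#' coh <- simulate_paired_cohort(seed = 42)
#' calibrate_level2(coh)
#' @export
simulate_paired_cohort <- function(groups = default_cohort_groups(),
                                   relation = linear_map(
                                     0.61, 0.39,
                                     from = "SUVR_PiB", to = "SUVR_FBB"),
                                   pib_noise_sd = 0.03,
                                   tracer_noise_sd = 0.0423,
                                   seed = 1L,
                                   tracer = "FBB") {
  stopifnot(inherits(relation, "linear_map"),
            is.numeric(pib_noise_sd), pib_noise_sd >= 0,
            is.numeric(tracer_noise_sd), tracer_noise_sd >= 0)
  if (!identical(relation$domain_scale, "SUVR_PiB")) {
    stop("relation must map from scale 'SUVR_PiB', got '",
         relation$domain_scale, "'", call. = FALSE)
  }
  if (!is.data.frame(groups) || nrow(groups) == 0L) {
    stop("groups must be a non-empty data frame", call. = FALSE)
  }
  stopifnot(all(c("group", "n", "mean_suvr_pib", "sd_suvr_pib") %in%
                  names(groups)),
            all(groups$n >= 1L), all(groups$sd_suvr_pib >= 0))

  total <- sum(groups$n)
  grp <- rep(groups$group, groups$n)
  mu <- rep(groups$mean_suvr_pib, groups$n)
  sg <- rep(groups$sd_suvr_pib, groups$n)

  withr::with_seed(seed, {
    true_pib <- stats::rnorm(total, mu, sg)
    true_tracer <- apply_map(relation, true_pib)
    obs_pib <- true_pib + stats::rnorm(total, 0, pib_noise_sd)
    obs_tracer <- true_tracer + stats::rnorm(total, 0, tracer_noise_sd)
  })

  out <- tibble::tibble(
    subject_id = sprintf("S%03d", seq_len(total)),
    group = grp,
    true_suvr_pib = true_pib,
    true_suvr_tracer = true_tracer,
    suvr_pib = obs_pib,
    suvr_tracer = obs_tracer
  )
  attr(out, "relation") <- relation
  attr(out, "tracer") <- tracer
  out
}

#' Write a simulated cohort as the paired-SUVR CSV dialect
#'
#' Writes the observed pairs (`subject_id, suvr_pib, suvr_tracer, group`) —
#' the dialect [run_calibrate()] reads — and the hidden ground truth as a
#' sidecar CSV.
#'
#' @param cohort Tibble from [simulate_paired_cohort()].
#' @param cohort_csv,truth_csv Output paths.
#' @return Named character vector of the two paths, invisibly.
#' @export
write_cohort <- function(cohort, cohort_csv, truth_csv = NULL) {
  readr::write_csv(
    cohort[, c("subject_id", "suvr_pib", "suvr_tracer", "group")],
    cohort_csv)
  if (!is.null(truth_csv)) {
    readr::write_csv(
      cohort[, c("subject_id", "group", "true_suvr_pib", "true_suvr_tracer")],
      truth_csv)
  }
  invisible(c(cohort = cohort_csv, truth = truth_csv %||% NA_character_))
}
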