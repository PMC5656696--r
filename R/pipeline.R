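#' @name pipeline
#' @title File-level pipeline steps
#' @description
#' Thin file-in/file-out wrappers around the quantification and calibration
#' functions: each reads standard formats (NIfTI-1 volumes, the paired-SUVR
#' CSV dialect), runs one pipeline stage and writes a CSV row or a
#' schema-versioned JSON report. They are what the `inst/cli/centiloid.R`
#' command-line script dispatches to, and they are usable directly from R.
#' Errors are signalled as conditions; the CLI translates them into non-zero
#' exit statuses.
NULL

REPORT_SCHEMA <- "centiloid-report/1"

write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

map_report <- function(map, cl_style = FALSE) {
  dp <- if (cl_style) 1L else 2L
  list(
    domain = map$domain_scale, range = map$range_scale,
    slope = map$m, intercept = map$b,
    rounded = list(
      slope = round(map$m, dp), intercept = round(map$b, dp),
      equation = format(map, digits = dp)
    )
  )
}

#' @rdname pipeline
#' @param pet,cortex,reference Paths to the spatially normalized PET volume
#'   and the cortical / whole-cerebellum VOI masks (NIfTI-1, shared grid).
#' @param out Output CSV path; one SUVR row is appended (header written when
#'   the file does not yet exist).
#' @param subject_id,tracer Labels for the emitted row.
#' @param threshold Mask binarization threshold (see [read_mask()]).
#' @return `run_suvr()`: the SUVR record tibble, invisibly.
#' @export
run_suvr <- function(pet, cortex, reference, out,
                     subject_id = "subject", tracer = "FBB",
                     threshold = 0.5) {
  vol <- read_volume(pet)
  ctx <- read_mask(cortex, threshold = threshold, name = "CL_cortex")
  ref <- read_mask(reference, threshold = threshold,
                   name = "whole_cerebellum")
  for (m in list(ctx, ref)) {
    if (!check_same_grid(vol, m)) {
      stop("grid mismatch between PET volume '", pet, "' and mask '",
           if (m$name == "CL_cortex") cortex else reference, "'",
           call. = FALSE)
    }
  }
  rec <- compute_suvr(vol, ctx, ref, subject_id = subject_id,
                      tracer = tracer)
  message(sprintf(
    "suvr: %s/%s target %d voxels, reference %d voxels, SUVR %.4f",
    subject_id, tracer, region_mean(vol, ctx)$voxel_count,
    region_mean(vol, ref)$voxel_count, rec$suvr))
  readr::write_csv(rec, out, append = file.exists(out),
                   col_names = !file.exists(out))
  invisible(rec)
}

#' @rdname pipeline
#' @param pairs Path to a paired-SUVR CSV with columns
#'   `subject_id, suvr_pib, suvr_tracer, group`.
#' @param out_json Output path for the JSON report.
#' @param standard_slope,standard_intercept Coefficients of the PiB-to-CL
#'   map (defaults: the published 93.7 and -94.6).
#' @param gate_r2 Calibration validity gate on R-squared (default 0.70). A
#'   failed gate is reported in the JSON, not raised as an error: QC is
#'   data.
#' @return `run_calibrate()`: the `level2_report`, invisibly.
#' @export
run_calibrate <- function(pairs, out_json, tracer = "FBB",
                          standard_slope = 93.7,
                          standard_intercept = -94.6,
                          gate_r2 = 0.70) {
  d <- readr::read_csv(pairs, show_col_types = FALSE)
  need <- c("subject_id", "suvr_pib", "suvr_tracer")
  if (!all(need %in% names(d))) {
    stop("malformed pairs CSV: need columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (nrow(d) < 3L) {
    stop("insufficient pairs: need at least 3 subjects, got ", nrow(d),
         call. = FALSE)
  }
  rep2 <- calibrate_level2(
    d, tracer = tracer,
    standard_map = standard_pib_map(standard_slope, standard_intercept),
    gate_r2 = gate_r2)
  report <- list(
    schema = REPORT_SCHEMA, kind = "level2_calibration",
    tracer = tracer, n = rep2$fit$n,
    config = list(pairs = pairs, standard_slope = standard_slope,
                  standard_intercept = standard_intercept,
                  gate_r2 = gate_r2),
    fit = c(map_report(rep2$fit$map),
            list(r_squared = rep2$fit$r_squared,
                 r_squared_rounded = round(rep2$fit$r_squared, 2),
                 residual_sd = rep2$fit$residual_sd)),
    pass_gate = rep2$pass_gate,
    to_pib = map_report(rep2$to_pib),
    direct_cl = map_report(rep2$direct_cl, cl_style = TRUE)
  )
  write_report_json(report, out_json)
  invisible(rep2)
}

#' @rdname pipeline
#' @param computed,reference_csv Paths to CSVs with columns
#'   `subject_id, cl`: the locally computed and the reference Centiloid
#'   values for the standard calibration scan set.
#' @return `run_validate()`: the `level1_report`, invisibly.
#' @export
run_validate <- function(computed, reference_csv, out_json) {
  dc <- readr::read_csv(computed, show_col_types = FALSE)
  dr <- readr::read_csv(reference_csv, show_col_types = FALSE)
  for (d in list(dc, dr)) {
    if (!all(c("subject_id", "cl") %in% names(d))) {
      stop("validation CSVs need columns subject_id, cl", call. = FALSE)
    }
  }
  only_c <- setdiff(dc$subject_id, dr$subject_id)
  only_r <- setdiff(dr$subject_id, dc$subject_id)
  if (length(only_c) || length(only_r)) {
    stop("unmatched subject ids: only in computed [",
         paste(only_c, collapse = ", "), "]; only in reference [",
         paste(only_r, collapse = ", "), "]", call. = FALSE)
  }
  d <- dplyr::inner_join(
    dplyr::rename(dc, cl_computed = "cl"),
    dplyr::rename(dr, cl_reference = "cl"), by = "subject_id")
  rep1 <- validate_level1(d, cl_computed, cl_reference)
  report <- list(
    schema = REPORT_SCHEMA, kind = "level1_validation",
    n = rep1$fit$n,
    criteria = rep1$criteria,
    fit = c(map_report(rep1$fit$map),
            list(r_squared = rep1$fit$r_squared)),
    pass = list(r2 = rep1$pass_r2, slope = rep1$pass_slope,
                intercept = rep1$pass_intercept,
                overall = rep1$pass_overall)
  )
  write_report_json(report, out_json)
  invisible(rep1)
}

#' @rdname pipeline
#' @param out_dir Output directory for `run_simulate()` (created if
#'   needed): writes `cohort.csv`, `truth.csv` and `config.json`, plus
#'   phantom NIfTI files when `write_phantom = TRUE`.
#' @param seed Integer seed for the generators.
#' @param relation_slope,relation_intercept Generating inter-tracer
#'   relation (PiB SUVR to tracer SUVR).
#' @param pib_noise_sd,tracer_noise_sd Observed-SUVR measurement noise SDs.
#' @param write_phantom Also write a noise-free phantom volume and its two
#'   masks as NIfTI-1.
#' @return `run_simulate()`: the cohort tibble, invisibly.
#' @export
run_simulate <- function(out_dir, seed = 1L, tracer = "FBB",
                         relation_slope = 0.61, relation_intercept = 0.39,
                         pib_noise_sd = 0.03, tracer_noise_sd = 0.0423,
                         write_phantom = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  relation <- linear_map(relation_slope, relation_intercept,
                         from = "SUVR_PiB", to = paste0("SUVR_", tracer))
  coh <- simulate_paired_cohort(
    relation = relation, pib_noise_sd = pib_noise_sd,
    tracer_noise_sd = tracer_noise_sd, seed = seed, tracer = tracer)
  write_cohort(coh, file.path(out_dir, "cohort.csv"),
               file.path(out_dir, "truth.csv"))
  if (write_phantom) {
    ph <- generate_phantom(seed = seed)
    write_volume(ph$volume, file.path(out_dir, "phantom.nii.gz"))
    write_mask(ph$cortex, file.path(out_dir, "phantom_cortex.nii.gz"))
    write_mask(ph$cerebellum,
               file.path(out_dir, "phantom_cerebellum.nii.gz"))
  }
  message("simulate: ", nrow(coh), " subjects written to ", out_dir,
          " (seed ", seed, ")")
  write_report_json(
    list(schema = REPORT_SCHEMA, kind = "simulation_config",
         seed = seed, tracer = tracer, n = nrow(coh),
         relation = list(slope = relation_slope,
                         intercept = relation_intercept),
         pib_noise_sd = pib_noise_sd, tracer_noise_sd = tracer_noise_sd,
         write_phantom = write_phantom),
    file.path(out_dir, "config.json"))
  invisible(coh)
}

#' @rdname pipeline
#' @param cl_csv Path to a CSV of Centiloid values with columns
#'   `subject_id, group, tracer, cl`.
#' @param k SD multiplier for the upper-normal-limit thresholds.
#' @param young_group Group label identifying the young, amyloid-free
#'   controls used for variance ratio and thresholds.
#' @return `run_cohort_stats()`: the per-group stats tibble, invisibly.
#' @export
run_cohort_stats <- function(cl_csv, out_json, k = 2,
                             young_group = "young_control") {
  d <- readr::read_csv(cl_csv, show_col_types = FALSE)
  if (!all(c("group", "tracer", "cl") %in% names(d))) {
    stop("cohort CSV needs columns group, tracer, cl", call. = FALSE)
  }
  stats <- cohort_stats(d, cl, group, tracer)
  young <- stats[stats$group == young_group, , drop = FALSE]
  thresholds <- NULL
  vr <- NULL
  if (nrow(young) > 0L) {
    thresholds <- lapply(seq_len(nrow(young)), function(i) {
      row <- young[i, , drop = FALSE]
      list(tracer = row$tracer,
           mean_cl = row$mean_cl, sd_cl = row$sd_cl,
           k_sd_only = upper_normal_limit(row, k = k, center = "zero"),
           mean_plus_k_sd = upper_normal_limit(row, k = k,
                                               center = "mean"))
    })
    pib <- young[young$tracer == "PiB", , drop = FALSE]
    others <- young[young$tracer != "PiB", , drop = FALSE]
    if (nrow(pib) == 1L && nrow(others) > 0L) {
      vr <- lapply(seq_len(nrow(others)), function(i) {
        list(tracer = others$tracer[i],
             ratio = variance_ratio(others[i, ], pib),
             ratio_rounded = round(variance_ratio(others[i, ], pib), 2))
      })
    }
  }
  report <- list(
    schema = REPORT_SCHEMA, kind = "cohort_stats",
    k = k, young_group = young_group,
    groups = stats,
    upper_normal_limits = thresholds,
    variance_ratio = vr
  )
  write_report_json(report, out_json)
  invisible(stats)
}
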