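#' Per-group Centiloid summary statistics
#'
#' Sample mean and SD (n-1 denominator) of Centiloid values, grouped by
#' cohort group and tracer. This is the QC summary behind the young-normal
#' variance ratio and the upper-normal-limit thresholds.
#'
#' @param data Data frame with one CL value per scan.
#' @param cl Column of `data` holding CL values (bare name; default `cl`).
#' @param ... Grouping columns (bare names), typically `group, tracer`.
#' @return A tibble with the grouping columns plus `n`, `mean_cl`, `sd_cl`,
#'   one row per group. Groups need `n >= 2` for the SD to be defined.
#' @examples
#' d <- data.frame(group = "young", tracer = "PiB", cl = c(-3, 0, 2, 1))
#' cohort_stats(d, cl, group, tracer)
#' @export
cohort_stats <- function(data, cl = cl, ...) {
  out <- data |>
    dplyr::group_by(...) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_cl = mean({{ cl }}),
      sd_cl = stats::sd({{ cl }}),
      .groups = "drop"
    )
  if (any(out$n < 2L)) {
    stop("each group needs at least 2 values for an SD; got n = ",
         paste(out$n[out$n < 2L], collapse = ", "), call. = FALSE)
  }
  out
}

#' Young-normal variance ratio between a tracer and PiB
#'
#' The ratio SD_tracer / SD_PiB of Centiloid values in young,
#' amyloid-free controls: a unit-free measure of a tracer's measurement
#' variability relative to the reference tracer. A ratio of 1.96, for
#' example, means the tracer's young-normal CL spread is about twice PiB's.
#'
#' @param tracer_stats,pib_stats Either one-row data frames with an `sd_cl`
#'   column (as returned by [cohort_stats()]) or bare numeric SDs.
#' @return The dimensionless ratio `sd_tracer / sd_pib`.
#' @examples
#' variance_ratio(6.81, 3.48)
#' @export
variance_ratio <- function(tracer_stats, pib_stats) {
  sd_of <- function(s, what) {
    if (is.data.frame(s)) {
      stopifnot(nrow(s) == 1L, "sd_cl" %in% names(s))
      s <- s$sd_cl
    }
    stopifnot(is.numeric(s), length(s) == 1L, is.finite(s))
    if (s < 0) stop("negative SD for ", what, call. = FALSE)
    s
  }
  sd_pib <- sd_of(pib_stats, "PiB")
  if (sd_pib == 0) stop("PiB SD is zero; variance ratio undefined", call. = FALSE)
  sd_of(tracer_stats, "tracer") / sd_pib
}

#' Upper limit of the normal Centiloid range
#'
#' One convention for declaring a scan amyloid-negative is a threshold `k`
#' standard deviations above the young-normal mean. Because the young-normal
#' mean is approximately 0 CL by construction of the scale, a pure `k x SD`
#' variant (`center = "zero"`) is exposed alongside `mean + k x SD`
#' (`center = "mean"`, the default); integer-rounded thresholds are the
#' convention for reporting.
#'
#' @param stats Data frame with columns `mean_cl` and `sd_cl` (any number of
#'   rows; vectorized), as returned by [cohort_stats()].
#' @param k SD multiplier (default 2).
#' @param rounding `"nearest"` (integer CL, the reporting convention) or
#'   `"none"`.
#' @param center `"mean"` for `mean_cl + k * sd_cl`, `"zero"` for
#'   `k * sd_cl` alone.
#' @return Numeric vector of CL thresholds, one per row of `stats`.
#' @examples
#' yn <- data.frame(mean_cl = c(-0.32, -1.08), sd_cl = c(3.48, 6.81))
#' upper_normal_limit(yn, center = "zero")
#' @export
upper_normal_limit <- function(stats, k = 2,
                               rounding = c("nearest", "none"),
                               center = c("mean", "zero")) {
  rounding <- match.arg(rounding)
  center <- match.arg(center)
  stopifnot(is.data.frame(stats), all(c("mean_cl", "sd_cl") %in% names(stats)),
            all(stats$sd_cl >= 0), is.numeric(k), length(k) == 1L)
  base <- if (center == "mean") stats$mean_cl else 0
  out <- base + k * stats$sd_cl
  if (rounding == "nearest") out <- round(out)
  out
}
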