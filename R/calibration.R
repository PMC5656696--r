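#' Fit a linear relation between two quantification scales
#'
#' Ordinary least squares of `y` on `x`, the regression form in which
#' inter-tracer Centiloid calibrations are published (tracer SUVR regressed
#' on PiB SUVR). `r_squared` is the squared Pearson correlation and
#' `residual_sd` uses the n-2 denominator. Deming regression (errors in both
#' variables, error-variance ratio `lambda`) is available via
#' `method = "deming"` for sensitivity analyses, but OLS is the default
#' because published calibration equations are OLS fits.
#'
#' @param data A data frame of paired observations.
#' @param x,y Columns of `data` holding the domain- and range-scale values
#'   (tidy evaluation: bare column names).
#' @param from,to Scale labels for the fitted [linear_map]; default to the
#'   column names.
#' @param method `"ols"` (default) or `"deming"`.
#' @param lambda Ratio of y-error variance to x-error variance for Deming
#'   regression (default 1, orthogonal regression).
#' @return An object of class `suvr_fit`: fields `map` ([linear_map]),
#'   `r_squared`, `n`, `residual_sd`, `method`, and the fitted data. Has
#'   [tidy()][generics::tidy], [glance()][generics::glance] and
#'   [autoplot()][ggplot2::autoplot] methods.
#' @examples
#' d <- data.frame(pib = c(1, 1.5, 2), fbb = 0.61 * c(1, 1.5, 2) + 0.39)
#' fit_ols(d, pib, fbb)
#' @export
fit_ols <- function(data, x, y, from = NULL, to = NULL,
                    method = c("ols", "deming"), lambda = 1) {
  method <- match.arg(method)
  xq <- rlang::enquo(x)
  yq <- rlang::enquo(y)
  xv <- rlang::eval_tidy(xq, data)
  yv <- rlang::eval_tidy(yq, data)
  from <- from %||% rlang::as_label(xq)
  to <- to %||% rlang::as_label(yq)
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]; yv <- yv[ok]
  n <- length(xv)
  if (n < 3L) stop("insufficient pairs: need at least 3, got ", n, call. = FALSE)
  if (stats::var(xv) == 0) stop("degenerate fit: x has zero variance", call. = FALSE)
  if (method == "ols") {
    fit <- stats::lm(yv ~ xv)
    m <- unname(stats::coef(fit)[2])
    b <- unname(stats::coef(fit)[1])
    res <- stats::residuals(fit)
  } else {
    m <- deming_slope(xv, yv, lambda)
    b <- mean(yv) - m * mean(xv)
    res <- yv - (m * xv + b)
  }
  r2 <- if (stats::var(yv) == 0) 1 else stats::cor(xv, yv)^2
  structure(
    list(
      map = linear_map(m, b, from = from, to = to),
      r_squared = r2,
      n = n,
      residual_sd = sqrt(sum(res^2) / (n - 2)),
      method = method,
      data = tibble::tibble(x = xv, y = yv)
    ),
    class = "suvr_fit"
  )
}

# Deming estimator: maximum-likelihood slope when both variables carry
# Gaussian error with variance ratio lambda = var(e_y)/var(e_x).
deming_slope <- function(x, y, lambda = 1) {
  sxx <- stats::var(x); syy <- stats::var(y); sxy <- stats::cov(x, y)
  if (sxy == 0) stop("degenerate fit: zero covariance", call. = FALSE)
  (syy - lambda * sxx + sqrt((syy - lambda * sxx)^2 + 4 * lambda * sxy^2)) /
    (2 * sxy)
}

#' @export
print.suvr_fit <- function(x, ...) {
  cat(sprintf("<suvr_fit (%s)> %s  (n = %d, R^2 = %.4f)\n",
              x$method, format(x$map, digits = 4), x$n, x$r_squared))
  invisible(x)
}

#' @rdname fit_ols
#' @param x A `suvr_fit` object (for `tidy()`/`glance()`).
#' @param ... Unused.
#' @method tidy suvr_fit
#' @export
tidy.suvr_fit <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$map$b, x$map$m)
  )
}

#' @rdname fit_ols
#' @method glance suvr_fit
#' @export
glance.suvr_fit <- function(x, ...) {
  tibble::tibble(
    slope = x$map$m, intercept = x$map$b,
    r_squared = x$r_squared, residual_sd = x$residual_sd,
    n = x$n, method = x$method
  )
}

#' Level-1 validation of a local Centiloid pipeline
#'
#' Level-1 validation checks that a local implementation of the standard
#' Centiloid method reproduces the reference CL values published with the
#' calibration PiB scan set. Computed CL is regressed on reference CL and
#' three criteria are applied: R-squared strictly above `r2_min`, slope
#' within `slope_range` (inclusive) and intercept within `intercept_range`
#' (inclusive). Defaults are the published acceptance bounds
#' (R^2 > 0.98, slope 0.98--1.02, intercept -2 to +2).
#'
#' @param data Data frame with one row per calibration scan.
#' @param computed,reference Columns of `data` holding the locally computed
#'   and the reference CL values (bare names).
#' @param r2_min Strict lower bound on R-squared.
#' @param slope_range,intercept_range Inclusive `[lo, hi]` bounds.
#' @return A `level1_report`: the `suvr_fit` of computed vs reference plus
#'   logical `pass_r2`, `pass_slope`, `pass_intercept`, `pass_overall`.
#' @export
validate_level1 <- function(data, computed, reference,
                            r2_min = 0.98,
                            slope_range = c(0.98, 1.02),
                            intercept_range = c(-2, 2)) {
  fit <- fit_ols(data, {{ reference }}, {{ computed }},
                 from = "CL_reference", to = "CL_computed")
  # inclusive bounds, guarded against floating round-off of an exact fit
  eps <- 1e-9
  pass_r2 <- fit$r_squared > r2_min
  pass_slope <- fit$map$m >= slope_range[1] - eps &&
    fit$map$m <= slope_range[2] + eps
  pass_intercept <- fit$map$b >= intercept_range[1] - eps &&
    fit$map$b <= intercept_range[2] + eps
  structure(
    list(
      fit = fit,
      criteria = list(r2_min = r2_min, slope_range = slope_range,
                      intercept_range = intercept_range),
      pass_r2 = pass_r2, pass_slope = pass_slope,
      pass_intercept = pass_intercept,
      pass_overall = pass_r2 && pass_slope && pass_intercept
    ),
    class = "level1_report"
  )
}

#' @export
print.level1_report <- function(x, ...) {
  flag <- function(p) if (p) "PASS" else "FAIL"
  cat("<level1_report> local pipeline vs reference Centiloid values\n")
  cat(sprintf("  fit: %s (n = %d)\n", format(x$fit$map, digits = 4), x$fit$n))
  cat(sprintf("  R^2 = %.4f > %.2f        %s\n",
              x$fit$r_squared, x$criteria$r2_min, flag(x$pass_r2)))
  cat(sprintf("  slope in [%.2f, %.2f]      %s\n",
              x$criteria$slope_range[1], x$criteria$slope_range[2],
              flag(x$pass_slope)))
  cat(sprintf("  intercept in [%g, %g]     %s\n",
              x$criteria$intercept_range[1], x$criteria$intercept_range[2],
              flag(x$pass_intercept)))
  cat(sprintf("  overall                  %s\n", flag(x$pass_overall)))
  invisible(x)
}

#' @rdname validate_level1
#' @param x A `level1_report` (for `tidy()`/`glance()`).
#' @param ... Unused.
#' @method glance level1_report
#' @export
glance.level1_report <- function(x, ...) {
  tibble::tibble(
    slope = x$fit$map$m, intercept = x$fit$map$b,
    r_squared = x$fit$r_squared, n = x$fit$n,
    pass_r2 = x$pass_r2, pass_slope = x$pass_slope,
    pass_intercept = x$pass_intercept, pass_overall = x$pass_overall
  )
}

#' @rdname validate_level1
#' @method tidy level1_report
#' @export
tidy.level1_report <- function(x, ...) glance.level1_report(x, ...)

#' Level-2 calibration of a tracer against PiB
#'
#' Derives the linear conversion from a non-PiB tracer's SUVR to Centiloid
#' units from paired same-subject scans analysed by the standard method. The
#' tracer SUVR is regressed on the PiB SUVR (the published orientation,
#' `SUVR_tracer = m x SUVR_PiB + b`); the fit must satisfy the Centiloid
#' method gate R^2 > 0.70 to be valid. The fitted relation is inverted to
#' give the "calculated PiB SUVR" map and composed with the standard
#' PiB-to-CL equation to yield the direct tracer-to-CL equation. Full
#' precision coefficients are composed — printed, rounded equations are
#' views, never inputs.
#'
#' A report is returned even when the gate fails (`pass_gate = FALSE`), so
#' that QC remains inspectable.
#'
#' @param data Data frame of paired SUVRs, one row per subject.
#' @param suvr_pib,suvr_tracer Columns of `data` with the paired SUVR values
#'   (bare names; defaults match the cohort CSV dialect).
#' @param tracer Tracer label used in scale names (default `"FBB"`).
#' @param standard_map [linear_map] from `"SUVR_PiB"` to `"CL"`; default
#'   [standard_pib_map()].
#' @param gate_r2 Strict lower R-squared bound for a valid calibration
#'   (default 0.70).
#' @param method,lambda Passed to [fit_ols()].
#' @return A `level2_report`: `tracer`, `fit` (`suvr_fit` of tracer on PiB),
#'   `pass_gate`, `to_pib` (tracer SUVR -> calculated PiB SUVR) and
#'   `direct_cl` (tracer SUVR -> CL) [linear_map]s.
#' @examples
#' coh <- simulate_paired_cohort(seed = 7)
#' calibrate_level2(coh)
#' @export
calibrate_level2 <- function(data, suvr_pib = suvr_pib,
                             suvr_tracer = suvr_tracer, tracer = "FBB",
                             standard_map = standard_pib_map(),
                             gate_r2 = 0.70,
                             method = c("ols", "deming"), lambda = 1) {
  stopifnot(inherits(standard_map, "linear_map"))
  scale_tracer <- paste0("SUVR_", tracer)
  fit <- fit_ols(data, {{ suvr_pib }}, {{ suvr_tracer }},
                 from = "SUVR_PiB", to = scale_tracer,
                 method = method, lambda = lambda)
  to_pib <- invert_map(fit$map)
  structure(
    list(
      tracer = tracer,
      fit = fit,
      gate_r2 = gate_r2,
      pass_gate = fit$r_squared > gate_r2,
      to_pib = to_pib,
      direct_cl = compose_maps(to_pib, standard_map),
      standard_map = standard_map
    ),
    class = "level2_report"
  )
}

#' @export
print.level2_report <- function(x, ...) {
  cat(sprintf("<level2_report> %s calibrated against PiB (n = %d)\n",
              x$tracer, x$fit$n))
  cat(sprintf("  fit:       %s\n", format(x$fit$map, digits = 2)))
  cat(sprintf("  R^2 = %.4f  gate (> %.2f): %s\n", x$fit$r_squared,
              x$gate_r2, if (x$pass_gate) "PASS" else "FAIL"))
  cat(sprintf("  to PiB:    %s\n", format(x$to_pib, digits = 4)))
  cat(sprintf("  direct CL: %s\n", format(x$direct_cl, digits = 1)))
  invisible(x)
}

#' @rdname calibrate_level2
#' @param x A `level2_report` (for `tidy()`/`glance()`).
#' @param ... Unused.
#' @method tidy level2_report
#' @export
tidy.level2_report <- function(x, ...) {
  maps <- list(fit = x$fit$map, to_pib = x$to_pib, direct_cl = x$direct_cl)
  tibble::tibble(
    relation = names(maps),
    domain = vapply(maps, function(m) m$domain_scale, character(1)),
    range = vapply(maps, function(m) m$range_scale, character(1)),
    slope = vapply(maps, function(m) m$m, numeric(1)),
    intercept = vapply(maps, function(m) m$b, numeric(1))
  )
}

#' @rdname calibrate_level2
#' @method glance level2_report
#' @export
glance.level2_report <- function(x, ...) {
  tibble::tibble(
    tracer = x$tracer,
    slope = x$fit$map$m, intercept = x$fit$map$b,
    r_squared = x$fit$r_squared, n = x$fit$n,
    pass_gate = x$pass_gate,
    cl_slope = x$direct_cl$m, cl_intercept = x$direct_cl$b
  )
}
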