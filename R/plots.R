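#' Plot a fitted scale relation
#'
#' Scatter of the fitted pairs with the least-squares line, annotated with
#' the fitted equation and R-squared.
#'
#' @param object A `suvr_fit` from [fit_ols()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot suvr_fit
#' @export
autoplot.suvr_fit <- function(object, ...) {
  d <- object$data
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_abline(slope = object$map$m, intercept = object$map$b,
                         colour = "steelblue") +
    ggplot2::labs(
      x = object$map$domain_scale, y = object$map$range_scale,
      title = format(object$map, digits = 2),
      subtitle = sprintf("n = %d, R² = %.3f", object$n, object$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a level-2 calibration
#'
#' The paired-SUVR scatter and fitted inter-tracer line, with the derived
#' direct Centiloid equation in the caption.
#'
#' @param object A `level2_report` from [calibrate_level2()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot level2_report
#' @export
autoplot.level2_report <- function(object, ...) {
  autoplot(object$fit) +
    ggplot2::labs(
      caption = sprintf("%s  |  gate R² > %.2f: %s",
                        format(object$direct_cl, digits = 1), object$gate_r2,
                        if (object$pass_gate) "pass" else "FAIL")
    )
}

#' Plot a level-1 validation
#'
#' Computed vs reference Centiloid values with the identity line (dashed)
#' and the fitted line; the subtitle reports the per-criterion outcomes.
#'
#' @param object A `level1_report` from [validate_level1()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot level1_report
#' @export
autoplot.level1_report <- function(object, ...) {
  autoplot(object$fit) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::labs(
      subtitle = sprintf(
        "R² %s, slope %s, intercept %s → overall %s",
        if (object$pass_r2) "pass" else "FAIL",
        if (object$pass_slope) "pass" else "FAIL",
        if (object$pass_intercept) "pass" else "FAIL",
        if (object$pass_overall) "PASS" else "FAIL")
    )
}
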