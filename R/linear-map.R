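#' Linear map between quantification scales
#'
#' A `linear_map` represents an affine relation `y = m * x + b` between two
#' named quantification scales, e.g. from a tracer SUVR scale to the
#' Centiloid (CL) scale. Maps can be applied, inverted and composed, which is
#' all the scale arithmetic the Centiloid method needs: the standard
#' PiB-to-CL equation, the fitted inter-tracer relation, and the direct
#' tracer-to-CL equation obtained by composing the two.
#'
#' @param slope Slope `m` of the relation (range units per domain unit).
#' @param intercept Intercept `b`, in units of the range scale.
#' @param from,to Labels for the domain and range scales, e.g. `"SUVR_PiB"`,
#'   `"CL"`. Used to check compatibility when composing maps.
#' @return An object of class `linear_map`.
#' @examples
#' pib <- standard_pib_map()
#' apply_map(pib, 94.6 / 93.7) # the zero-CL anchor
#' @export
linear_map <- function(slope, intercept, from = "x", to = "y") {
  stopifnot(is.numeric(slope), length(slope) == 1L, is.finite(slope),
            is.numeric(intercept), length(intercept) == 1L, is.finite(intercept))
  structure(
    list(m = as.numeric(slope), b = as.numeric(intercept),
         domain_scale = as.character(from), range_scale = as.character(to)),
    class = "linear_map"
  )
}

#' @export
print.linear_map <- function(x, ...) {
  cat(sprintf("<linear_map> %s = %.6g x %s %+.6g\n",
              x$range_scale, x$m, x$domain_scale, x$b))
  invisible(x)
}

#' @export
format.linear_map <- function(x, digits = 1, ...) {
  sprintf(paste0("%s = %.", digits, "f x %s %+.", digits, "f"),
          x$range_scale, x$m, x$domain_scale, x$b)
}

#' Standard PiB SUVR to Centiloid conversion
#'
#' The published linear equation anchoring the Centiloid scale for
#' \eqn{^{11}}C-PiB analysed by the standard method (whole cerebellum
#' reference, 50--70 min acquisition): `CL = 93.7 x SUVR_PiB - 94.6`.
#' Its roots define the scale anchors: SUVR 94.6/93.7 (about 1.0096) maps to
#' 0 CL (young-normal mean) and SUVR 194.6/93.7 (about 2.0768) to 100 CL
#' (mild-AD mean).
#'
#' @param slope,intercept Override the standard coefficients, e.g. for a
#'   sensitivity analysis. Defaults are the published values.
#' @return A [linear_map] from scale `"SUVR_PiB"` to `"CL"`.
#' @export
standard_pib_map <- function(slope = 93.7, intercept = -94.6) {
  linear_map(slope, intercept, from = "SUVR_PiB", to = "CL")
}

#' Apply a linear map to values on its domain scale
#'
#' @param map A [linear_map].
#' @param x Numeric vector on the map's domain scale.
#' @return `map$m * x + map$b`, on the range scale.
#' @export
apply_map <- function(map, x) {
  stopifnot(inherits(map, "linear_map"), is.numeric(x))
  map$m * x + map$b
}

#' Invert a linear map
#'
#' Returns the map going the other way: if `y = m x + b` then
#' `x = (y - b) / m`. This is how a fitted tracer-vs-PiB relation is turned
#' into the "calculated PiB SUVR" conversion.
#'
#' @param map A [linear_map] with non-zero slope.
#' @return A [linear_map] with slope `1/m`, intercept `-b/m`, and the scale
#'   labels swapped.
#' @export
invert_map <- function(map) {
  stopifnot(inherits(map, "linear_map"))
  if (map$m == 0) {
    stop("cannot invert a linear_map with zero slope", call. = FALSE)
  }
  linear_map(1 / map$m, -map$b / map$m,
             from = map$range_scale, to = map$domain_scale)
}

#' Compose two linear maps
#'
#' `compose_maps(inner, outer)` returns the map `x -> outer(inner(x))`. The
#' inner map's range scale must match the outer map's domain scale; the
#' Centiloid use case is composing the inverted inter-tracer relation
#' (tracer SUVR -> PiB SUVR) with the standard PiB-to-CL map to obtain the
#' direct tracer-to-CL equation.
#'
#' @param inner,outer [linear_map]s with `inner$range_scale ==
#'   outer$domain_scale`.
#' @return A [linear_map] with slope `outer$m * inner$m` and intercept
#'   `outer$m * inner$b + outer$b`.
#' @export
compose_maps <- function(inner, outer) {
  stopifnot(inherits(inner, "linear_map"), inherits(outer, "linear_map"))
  if (!identical(inner$range_scale, outer$domain_scale)) {
    stop(sprintf("scale mismatch: inner map produces '%s' but outer map expects '%s'",
                 inner$range_scale, outer$domain_scale), call. = FALSE)
  }
  linear_map(outer$m * inner$m, outer$m * inner$b + outer$b,
             from = inner$domain_scale, to = outer$range_scale)
}
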