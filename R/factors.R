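#' Define an experimental factor and its axis scaling
#'
#' A factor specification carries the physical bounds of one axis of the
#' experimental parameter space (e.g. glucose in g/l, pH, acetic acid in mM)
#' together with the transformation used to map it onto the unit interval.
#' All design construction and response-surface modelling operate in these
#' transformed coordinates, so the choice of scale encodes an a-priori
#' assumption about where the system is most sensitive: concentration axes
#' of biochemical systems often vary most at low concentrations and are
#' therefore given a logarithmic scale with an additive offset so that zero
#' concentrations remain representable.
#'
#' @param name Axis label, e.g. `"acetic_acid_mM"`.
#' @param lower,upper Bounds in natural factor units; `lower < upper`.
#' @param scale `"linear"` or `"log"` (logarithmic with offset).
#' @param offset Additive offset for the log scale (default 1 factor unit);
#'   must satisfy `lower + offset > 0`. Ignored for linear axes.
#' @return An object of class `"factor_spec"`.
#' @examples
#' factor_spec("acetic_acid_mM", 0, 120, scale = "log")
#' @export
factor_spec <- function(name, lower, upper, scale = c("linear", "log"),
                        offset = 1) {
  scale <- match.arg(scale)
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(lower), is.numeric(upper),
            length(lower) == 1L, length(upper) == 1L)
  if (!is.finite(lower) || !is.finite(upper) || lower >= upper)
    stop("factor '", name, "': need finite lower < upper", call. = FALSE)
  if (scale == "log") {
    if (!is.finite(offset) || offset < 0)
      stop("factor '", name, "': log offset must be a finite value >= 0",
           call. = FALSE)
    if (lower + offset <= 0)
      stop("factor '", name, "': lower + offset must be positive for a log axis",
           call. = FALSE)
  }
  structure(list(name = name, lower = lower, upper = upper,
                 scale = scale, offset = if (scale == "log") offset else 0),
            class = "factor_spec")
}

#' @export
print.factor_spec <- function(x, ...) {
  cat(sprintf("factor '%s': [%g, %g], %s scale%s\n", x$name, x$lower, x$upper,
              x$scale,
              if (x$scale == "log") sprintf(" (offset %g)", x$offset) else ""))
  invisible(x)
}

#' Map factor values onto the unit interval
#'
#' Linear axes map affinely: `(value - lower) / (upper - lower)`. Logarithmic
#' axes map `log(value + offset)` affinely so that `lower` goes to 0 and
#' `upper` to 1. Both maps are strictly increasing and exactly invertible by
#' [inverse_axis()].
#'
#' @param value Numeric vector of values in natural factor units, each within
#'   `[lower, upper]`.
#' @param spec A [factor_spec()].
#' @return Numeric vector of transformed coordinates in \eqn{[0, 1]}.
#' @export
transform_axis <- function(value, spec) {
  stopifnot(inherits(spec, "factor_spec"), is.numeric(value))
  tol <- 1e-9 * (spec$upper - spec$lower)
  if (any(value < spec$lower - tol | value > spec$upper + tol, na.rm = TRUE))
    stop("value outside [", spec$lower, ", ", spec$upper, "] for factor '",
         spec$name, "'", call. = FALSE)
  value <- pmin(pmax(value, spec$lower), spec$upper)
  if (spec$scale == "linear") {
    (value - spec$lower) / (spec$upper - spec$lower)
  } else {
    if (any(value + spec$offset <= 0, na.rm = TRUE))
      stop("non-positive argument to log transform for factor '", spec$name,
           "'", call. = FALSE)
    (log(value + spec$offset) - log(spec$lower + spec$offset)) /
      (log(spec$upper + spec$offset) - log(spec$lower + spec$offset))
  }
}

#' Invert an axis transformation
#'
#' @param coord Numeric vector of transformed coordinates in \eqn{[0, 1]}.
#' @param spec A [factor_spec()].
#' @return Values in natural factor units; `inverse_axis(transform_axis(v), s)`
#'   round-trips to machine precision.
#' @export
inverse_axis <- function(coord, spec) {
  stopifnot(inherits(spec, "factor_spec"), is.numeric(coord))
  if (any(coord < -1e-9 | coord > 1 + 1e-9, na.rm = TRUE))
    stop("transformed coordinate outside [0, 1] for factor '", spec$name, "'",
         call. = FALSE)
  coord <- pmin(pmax(coord, 0), 1)
  if (spec$scale == "linear") {
    spec$lower + coord * (spec$upper - spec$lower)
  } else {
    lo <- log(spec$lower + spec$offset)
    hi <- log(spec$upper + spec$offset)
    exp(lo + coord * (hi - lo)) - spec$offset
  }
}

#' Default factor set for the acetic-acid toxicity assay
#'
#' The standard three-factor space the batch-culture experiments cover:
#' glucose 0--40 g/l (0--4% w/v) on a log-with-offset axis (growth responds
#' to relative changes in sugar), pH 2.5--7 linear, and acetic acid
#' 0--120 mM linear (uniform dose resolution for EC50 estimation).
#'
#' @return List of three [factor_spec()] objects.
#' @export
default_factors <- function() {
  list(factor_spec("glucose_g_l", 0, 40, scale = "log", offset = 1),
       factor_spec("ph", 2.5, 7, scale = "linear"),
       factor_spec("acetic_acid_mM", 0, 120, scale = "linear"))
}
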