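#' Two-point oxygen-sensor calibration
#'
#' Optical oxygen sensors are calibrated against two standards: oxygen-free
#' water (sodium-sulfite scavenged) and air-saturated water. With only two
#' calibration points the defensible model is affine in the signal; an
#' optional Stern-Volmer mode is available when a quenching constant is
#' known from the sensor datasheet.
#'
#' @param signal_zero Sensor reading in the oxygen-free standard.
#' @param signal_air Sensor reading in the air-saturated standard.
#' @param ksv Optional Stern-Volmer quenching constant (per % air
#'   saturation); if supplied, the inverse Stern-Volmer relation is used
#'   instead of the affine map.
#' @return Object of class `"o2_calibration"`.
#' @export
o2_calibration <- function(signal_zero, signal_air, ksv = NULL) {
  stopifnot(is.numeric(signal_zero), is.numeric(signal_air))
  if (signal_zero == signal_air)
    stop("degenerate calibration: identical zero and air readings",
         call. = FALSE)
  if (!is.null(ksv) && ksv <= 0)
    stop("Stern-Volmer constant must be positive", call. = FALSE)
  structure(list(signal_zero = signal_zero, signal_air = signal_air,
                 ksv = ksv),
            class = "o2_calibration")
}

#' Convert oxygen-sensor signals to saturation and partial pressure
#'
#' Air saturation is `100 * (signal - signal_zero) / (signal_air -
#' signal_zero)` (affine two-point model), clamped to \eqn{[-5, 110]} and
#' flagged when outside the physical \eqn{[0, 100]} range. The oxygen
#' partial pressure follows from the saturation, the oxygen mole fraction
#' of air (0.2095) and the dry-gas pressure, i.e. ambient pressure minus
#' the water-vapor pressure at the incubation temperature (42.4 hPa at
#' 30 degrees C).
#'
#' @param cal An [o2_calibration()].
#' @param signal Numeric vector of raw sensor readings.
#' @param ambient_hPa Ambient pressure (default 1013 hPa).
#' @param vapor_hPa Water-vapor pressure at culture temperature (default
#'   42.4 hPa, 30 degrees C).
#' @return `data.frame` with columns `saturation_percent`, `pO2_hPa` and
#'   logical `out_of_range`. Units are recorded in the `"units"` attribute.
#' @examples
#' cal <- o2_calibration(signal_zero = 3.1, signal_air = 28.7)
#' o2_signal_to_saturation(cal, c(3.1, 28.7))
#' @export
o2_signal_to_saturation <- function(cal, signal, ambient_hPa = 1013,
                                    vapor_hPa = 42.4) {
  stopifnot(inherits(cal, "o2_calibration"), is.numeric(signal))
  if (is.null(cal$ksv)) {
    sat <- 100 * (signal - cal$signal_zero) / (cal$signal_air - cal$signal_zero)
  } else {
    # inverse Stern-Volmer: signal ~ signal_zero / (1 + ksv * sat)
    sat <- (cal$signal_zero / signal - 1) / cal$ksv
  }
  flagged <- sat < 0 | sat > 100
  sat <- pmin(pmax(sat, -5), 110)
  p <- sat / 100 * 0.2095 * (ambient_hPa - vapor_hPa)
  out <- data.frame(saturation_percent = sat, pO2_hPa = p,
                    out_of_range = flagged)
  attr(out, "units") <- c(saturation_percent = "%", pO2_hPa = "hPa")
  out
}

#' Ratiometric pHluorin calibration
#'
#' Cytosolic pH is reported by the pHluorin fluorescence ratio (excitation
#' 390 nm over 480 nm, emission 510 nm), calibrated against buffers of
#' defined pH (typically 5.0 to 8.0 in 0.5 steps). A shape-preserving
#' monotone piecewise-cubic interpolant through the (pH, ratio) pairs is
#' invertible over the calibrated range, so measured ratios convert back to
#' pH without assuming a parametric sigmoid.
#'
#' @param ph_knots Calibration pH values, strictly increasing, at least 4
#'   spanning at least 2 pH units.
#' @param ratio_knots Fluorescence ratios at each pH, strictly monotone.
#' @return Object of class `"ph_calibration"` with forward (`ratio(ph)`)
#'   and inverse (`ph(ratio)`) maps.
#' @examples
#' cal <- ph_calibration(seq(5, 8, 0.5),
#'                       0.5 + 2 / (1 + 10^(6.8 - seq(5, 8, 0.5))))
#' @export
ph_calibration <- function(ph_knots, ratio_knots) {
  stopifnot(is.numeric(ph_knots), is.numeric(ratio_knots))
  if (length(ph_knots) < 4L)
    stop("need at least 4 calibration pairs", call. = FALSE)
  if (diff(range(ph_knots)) < 2)
    stop("calibration must span at least 2 pH units", call. = FALSE)
  interp <- monotone_interpolant(ph_knots, ratio_knots)
  structure(list(interp = interp, ph_knots = ph_knots,
                 ratio_knots = ratio_knots),
            class = "ph_calibration")
}

#' @export
print.ph_calibration <- function(x, ...) {
  cat(sprintf("pHluorin calibration: %d knots, pH %.1f .. %.1f, ratio %.3g .. %.3g\n",
              length(x$ph_knots), min(x$ph_knots), max(x$ph_knots),
              min(x$ratio_knots), max(x$ratio_knots)))
  invisible(x)
}

#' Forward-evaluate a pH calibration
#'
#' @param cal A [ph_calibration()].
#' @param ph pH values within the calibrated range.
#' @return Fluorescence ratios.
#' @export
ph_to_ratio <- function(cal, ph) {
  stopifnot(inherits(cal, "ph_calibration"))
  cal$interp$fun(ph)
}

#' Convert a fluorescence-ratio series to intracellular pH
#'
#' Pointwise inversion of the calibration interpolant. Ratios overshooting
#' the calibrated range by up to 2% of the ratio span are clamped to the
#' range edge and flagged; ratios further outside become missing values
#' (also flagged) rather than raising an error, so a single saturated
#' reading does not abort a whole plate.
#'
#' @param cal A [ph_calibration()].
#' @param ratio Numeric vector of measured 390/480 ratios.
#' @return `data.frame` with columns `ph` (pH units, `NA` where the ratio
#'   was far out of range) and logical `flagged`.
#' @export
ratio_to_ph <- function(cal, ratio) {
  stopifnot(inherits(cal, "ph_calibration"), is.numeric(ratio))
  rlo <- min(cal$ratio_knots); rhi <- max(cal$ratio_knots)
  span <- rhi - rlo
  tol <- 0.02 * span
  far <- ratio < rlo - tol | ratio > rhi + tol
  flagged <- far | ratio < rlo | ratio > rhi
  clamped <- pmin(pmax(ratio, rlo), rhi)
  ph <- rep(NA_real_, length(ratio))
  ok <- !far & !is.na(ratio)
  if (any(ok)) ph[ok] <- cal$interp$inv(clamped[ok])
  out <- data.frame(ph = ph, flagged = flagged)
  attr(out, "units") <- c(ph = "pH")
  out
}

#' A synthetic pHluorin calibration table
#'
#' A sigmoidal ratio-vs-pH curve sampled at the standard calibration pH
#' steps (5.0 to 8.0 by 0.5). This is a synthetic stand-in with a realistic
#' shape for examples and simulation, not a measured instrument
#' calibration.
#'
#' @return A [ph_calibration()].
#' @export
default_ph_calibration <- function() {
  ph <- seq(5, 8, by = 0.5)
  ratio <- 0.5 + 2 / (1 + 10^(6.8 - ph))
  ph_calibration(ph, ratio)
}
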