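#' Blank-correct and floor an optical-density series
#'
#' Subtracts the medium blank from every reading and replaces values below a
#' small positive floor so that the logarithm used by the growth-rate
#' estimator is defined everywhere.
#'
#' @param values Raw OD620 readings.
#' @param blank Blank OD to subtract (default 0).
#' @param floor Minimum retained OD (default 0.01); must be positive.
#' @return Corrected OD vector, all values `>= floor`.
#' @export
preprocess_od <- function(values, blank = 0, floor = 0.01) {
  stopifnot(is.numeric(values), is.numeric(blank), is.numeric(floor))
  if (floor <= 0)
    stop("'floor' must be positive so log(OD) is defined", call. = FALSE)
  if (blank >= min(values))
    stop("'blank' at or above the smallest raw reading; check calibration",
         call. = FALSE)
  pmax(values - blank, floor)
}

#' Area under a curve by the trapezoid rule
#'
#' The scalar summary used throughout the toxicity analysis: the OD integral
#' (or oxygen integral) is the trapezoidal area under the growth (or oxygen
#' saturation) curve,
#' \deqn{\sum_{i=2}^{n} \tfrac12 (v_i + v_{i-1}) (t_i - t_{i-1}).}
#' The same primitive integrates dose-response curves over the acetic-acid
#' axis. It is linear in the values and additive over contiguous partitions
#' of the abscissa.
#'
#' @param times Strictly increasing abscissa (hours, or mM for dose-response
#'   curves); length at least 2.
#' @param values Ordinates, same length.
#' @return The trapezoid area in ordinate-times-abscissa units.
#' @examples
#' curve_integral(0:10, rep(1, 11)) # 10
#' @export
curve_integral <- function(times, values) {
  stopifnot(is.numeric(times), is.numeric(values),
            length(times) == length(values))
  if (length(times) < 2L)
    stop("need at least two points", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("'times' must be strictly increasing", call. = FALSE)
  n <- length(times)
  sum(0.5 * (values[-1L] + values[-n]) * diff(times))
}

#' Growth kinetics from an OD time series
#'
#' Estimates the specific growth rate over time by piecewise linear
#' regression of log OD: exponential growth `dOD/dt = mu(t) OD(t)` implies
#' `ln OD(t) = ln OD(t0) + mu t`, so the least-squares slope of `ln OD`
#' against time inside a sliding window of `window` consecutive readings is
#' the local exponential rate constant. The window is centred (stride 1) and
#' each rate is assigned to the window's central time. Derived summaries are
#' the maximal rate and its time (earliest window wins ties), the biomass
#' yield (maximal OD minus the inoculum OD, removing the fixed starting
#' density from the yield), and the trapezoidal OD integral.
#'
#' @param times_min Reading times in minutes since inoculation, strictly
#'   increasing.
#' @param od Blank-corrected OD620 values, all positive.
#' @param window Odd number of points per regression window (default 5,
#'   i.e. 50 min at a 10-min cadence).
#' @return Object of class `"growth_kinetics"`: list with `mu_times` (h),
#'   `mu_values` (1/h), `mu_max`, `t_mu_max`, `biomass_yield`, `od_integral`.
#' @examples
#' t <- seq(0, 600, by = 10)
#' od <- 0.2 * exp(0.3 * t / 60)
#' k <- growth_kinetics(t, od)
#' k$mu_max # 0.3
#' @export
growth_kinetics <- function(times_min, od, window = 5L) {
  stopifnot(is.numeric(times_min), is.numeric(od),
            length(times_min) == length(od))
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("'window' must be an odd integer >= 3", call. = FALSE)
  if (length(od) < window)
    stop("series shorter than the regression window", call. = FALSE)
  if (any(diff(times_min) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (any(od <= 0))
    stop("all OD values must be positive; run preprocess_od() first",
         call. = FALSE)
  t_h <- times_min / 60
  logod <- log(od)
  n <- length(od)
  nw <- n - window + 1L
  half <- (window - 1L) %/% 2L
  mu <- numeric(nw)
  ctr <- numeric(nw)
  for (i in seq_len(nw)) {
    idx <- i:(i + window - 1L)
    tt <- t_h[idx]
    yy <- logod[idx]
    tc <- tt - mean(tt)
    mu[i] <- sum(tc * (yy - mean(yy))) / sum(tc^2)
    ctr[i] <- t_h[i + half]
  }
  imax <- which.max(mu) # first maximum on ties
  structure(list(
    mu_times = ctr, mu_values = mu,
    mu_max = mu[imax], t_mu_max = ctr[imax],
    biomass_yield = max(od) - od[1L],
    od_integral = curve_integral(t_h, od),
    window = window
  ), class = "growth_kinetics")
}

#' @export
print.growth_kinetics <- function(x, ...) {
  cat(sprintf(
    "growth kinetics: mu_max %.4f 1/h at %.2f h, yield %.3f OD, OD integral %.3f OD.h\n",
    x$mu_max, x$t_mu_max, x$biomass_yield, x$od_integral))
  invisible(x)
}

#' Per-well kinetics from a long plate table
#'
#' Applies [preprocess_od()] and [growth_kinetics()] to every OD620 well of a
#' long-format plate table and returns one summary row per well with the
#' condition metadata carried through. Oxygen-saturation wells get their
#' trapezoidal integral only (`o2_integral`).
#'
#' @param plate A plate table as returned by [read_plate_table()] or
#'   [simulate_experiment()].
#' @param window,blank,floor Passed to the per-well estimators.
#' @return `data.frame` with columns `well, strain, glucose_g_l, ph,
#'   acetic_acid_mM, channel, mu_max_per_h, t_mu_max_h, yield_od,
#'   od_integral` (OD wells) or `o2_integral` (oxygen wells).
#' @export
kinetics_table <- function(plate, window = 5L, blank = 0, floor = 0.01) {
  validate_plate_table(plate)
  keys <- unique(plate[, c("well", "strain", "glucose_g_l", "ph",
                           "acetic_acid_mM", "channel")])
  keys <- keys[keys$channel %in% c("OD620", "O2_saturation"), , drop = FALSE]
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    sub <- plate[plate$well == k$well & plate$channel == k$channel, ]
    sub <- sub[order(sub$time_min), ]
    out <- data.frame(k, mu_max_per_h = NA_real_, t_mu_max_h = NA_real_,
                      yield_od = NA_real_, od_integral = NA_real_,
                      o2_integral = NA_real_)
    if (k$channel == "OD620") {
      od <- preprocess_od(sub$value, blank = blank, floor = floor)
      gk <- growth_kinetics(sub$time_min, od, window = window)
      out$mu_max_per_h <- gk$mu_max
      out$t_mu_max_h <- gk$t_mu_max
      out$yield_od <- gk$biomass_yield
      out$od_integral <- gk$od_integral
    } else {
      out$o2_integral <- curve_integral(sub$time_min / 60, sub$value)
    }
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
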