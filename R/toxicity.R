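#' Dose-response slice along the acetic-acid axis
#'
#' Predicts the response surface along a dense acetic-acid grid at fixed pH,
#' glucose (and any further pinned factors), yielding the dose-response
#' curve from which EC50 and toxicity integrals are computed. The grid is
#' linear in mM so the toxicity integral is an area in response-units times
#' mM.
#'
#' @param model A fitted [gp_rsm()] model containing an acetic-acid axis.
#' @param fixed Named list pinning every other factor (natural units).
#' @param acid_axis Name of the acetic-acid factor (default
#'   `"acetic_acid_mM"`).
#' @param acid_max Upper end of the grid; defaults to the factor's upper
#'   bound.
#' @param grid Number of grid points (default 101).
#' @return Object of class `"dose_response"`: `data.frame` with columns
#'   `acid_mM` and `response`, fixed condition in the `"fixed"` attribute.
#' @export
dose_response <- function(model, fixed, acid_axis = "acetic_acid_mM",
                          acid_max = NULL, grid = 101L) {
  stopifnot(inherits(model, "gp_rsm"))
  if (!acid_axis %in% model$axes)
    stop("model has no axis '", acid_axis, "'", call. = FALSE)
  spec <- model$factors[[match(acid_axis, model$axes)]]
  if (is.null(acid_max)) acid_max <- spec$upper
  conc <- seq(spec$lower, acid_max, length.out = as.integer(grid))
  nd <- as.data.frame(fixed)[rep(1L, length(conc)), , drop = FALSE]
  nd[[acid_axis]] <- conc
  pr <- predict(model, nd, se.fit = FALSE)
  out <- data.frame(acid_mM = conc, response = pr$mean)
  attr(out, "fixed") <- fixed
  class(out) <- c("dose_response", "data.frame")
  out
}

#' Half-inhibition concentration (EC50) of a dose-response curve
#'
#' The EC50 is the acetic-acid concentration at which the response crosses
#' the midpoint between its maximum and minimum over the curve,
#' `(max + min) / 2`. Scanning from the low-acid side, the first grid
#' segment bracketing the midpoint level is located and the crossing is
#' linearly interpolated inside it; taking the first crossing makes the
#' estimate the lowest effective dose when the curve is non-monotone. A
#' curve that never reaches the level — or a flat curve, where the level is
#' undefined — yields `NA` with an explanatory flag.
#'
#' Because the level is self-normalizing, a curve showing only negligible
#' inhibition over the whole grid would still formally cross its own
#' midpoint; such an EC50 reflects noise, not toxicity, so curves whose
#' total relative effect `(max - min) / max(|response|)` stays below
#' `min_effect` are also flagged undefined (the half-inhibitory dose then
#' lies beyond the tested range).
#'
#' EC50 is invariant under positive affine transformations of the response,
#' so it can be computed on raw or normalized integrals alike.
#'
#' @param conc Strictly increasing concentration grid (mM), or a
#'   `"dose_response"` object.
#' @param response Responses on the grid (ignored when `conc` is a
#'   `"dose_response"`).
#' @param min_effect Minimal relative effect size below which the EC50 is
#'   reported undefined (default 0, no guard, which keeps the estimate
#'   invariant under affine response transforms; [toxicity_table()] uses
#'   0.05 because integral responses have a true zero).
#' @return List with `ec50` (mM or `NA`), `level` (the midpoint response
#'   level) and `flag` (`"ok"`, `"flat"` or `"no_crossing"`).
#' @examples
#' ec50(seq(0, 100, 1), seq(2, 0, length.out = 101))$ec50 # 50
#' @export
ec50 <- function(conc, response = NULL, min_effect = 0) {
  if (inherits(conc, "dose_response")) {
    response <- conc$response
    conc <- conc$acid_mM
  }
  stopifnot(is.numeric(conc), is.numeric(response),
            length(conc) == length(response))
  if (length(conc) < 3L)
    stop("need at least 3 points on the dose-response curve", call. = FALSE)
  if (any(diff(conc) <= 0))
    stop("concentration grid must be strictly increasing", call. = FALSE)
  hi <- max(response); lo <- min(response)
  if (hi == lo || (max(abs(response)) > 0 &&
                   (hi - lo) / max(abs(response)) < min_effect))
    return(list(ec50 = NA_real_, level = NA_real_, flag = "flat"))
  level <- (hi + lo) / 2
  s <- response - level
  for (i in seq_len(length(conc) - 1L)) {
    if (s[i] == 0)
      return(list(ec50 = conc[i], level = level, flag = "ok"))
    if (s[i] * s[i + 1L] < 0) {
      w <- s[i] / (s[i] - s[i + 1L])
      return(list(ec50 = conc[i] + w * (conc[i + 1L] - conc[i]),
                  level = level, flag = "ok"))
    }
  }
  if (s[length(s)] == 0)
    return(list(ec50 = conc[length(conc)], level = level, flag = "ok"))
  list(ec50 = NA_real_, level = level, flag = "no_crossing")
}

#' Toxicity integral of a dose-response curve
#'
#' The area below the response-vs-acetic-acid curve (trapezoid rule with
#' concentration as the abscissa). Large areas mean the response is retained
#' over the acid range; after per-strain normalization this becomes the
#' relative viability.
#'
#' @param conc Concentration grid (mM) or a `"dose_response"` object.
#' @param response Responses (ignored for a `"dose_response"`).
#' @return Area in response-units times mM.
#' @export
toxicity_integral <- function(conc, response = NULL) {
  if (inherits(conc, "dose_response")) {
    response <- conc$response
    conc <- conc$acid_mM
  }
  curve_integral(conc, response)
}

#' Per-strain relative viability
#'
#' Normalizes toxicity integrals to the highest value within each
#' (strain, channel) group, yielding a dimensionless sensitivity summary in
#' \eqn{[0, 1]}: the relative growth viability (OD channel) or relative
#' mitochondria viability (oxygen channel). The per-group maximum maps to
#' exactly 1; normalization is invariant under rescaling all integrals in a
#' group by a positive constant.
#'
#' @param integrals Numeric vector of toxicity integrals, all `>= 0`.
#' @param strain Character/factor grouping vector (recycled if length 1).
#' @param channel Optional second grouping vector (measurement channel).
#' @return Numeric vector of relative viabilities in \eqn{[0, 1]}; groups
#'   whose integrals are all zero yield `NA` with a warning.
#' @examples
#' relative_viability(c(2, 1, 0.5), strain = "wt") # 1.0 0.5 0.25
#' @export
relative_viability <- function(integrals, strain = "all", channel = "all") {
  stopifnot(is.numeric(integrals), length(integrals) >= 1L)
  if (any(integrals < 0))
    stop("toxicity integrals must be nonnegative", call. = FALSE)
  grp <- interaction(rep_len(strain, length(integrals)),
                     rep_len(channel, length(integrals)), drop = TRUE)
  mx <- stats::ave(integrals, grp, FUN = max)
  out <- ifelse(mx > 0, integrals / mx, NA_real_)
  if (anyNA(out))
    warning("all-zero integrals in at least one group; viability undefined",
            call. = FALSE)
  out
}

#' Toxicity metrics over a grid of fixed conditions
#'
#' Sweeps dose-response slices of a fitted integral surface over
#' combinations of pH and glucose, computing EC50, toxicity integral and
#' (within the table) relative viability for each. For oxygen-integral
#' surfaces a high integral means low oxygen consumption, i.e. respiratory
#' inhibition; setting `direction = "o2"` first reflects the curve as
#' `max(response) - response` so that the derived viability decreases with
#' inhibition for both channels (recorded in the `flags` column).
#'
#' @param model Fitted [gp_rsm()] integral surface for one strain and
#'   channel.
#' @param ph,glucose_g_l Numeric vectors of fixed values to sweep.
#' @param strain,channel Labels recorded in the output.
#' @param direction `"od"` (response already decreases with inhibition) or
#'   `"o2"` (reflect the curve first).
#' @param acid_axis,acid_max,grid Passed to [dose_response()].
#' @param min_effect Relative-effect guard passed to [ec50()]; default
#'   0.05 (curves with under 5% total inhibition get no EC50).
#' @return `data.frame` with one row per (pH, glucose) combination:
#'   `strain, channel, ph, glucose_g_l, ec50_mM, toxicity_integral,
#'   relative_viability, flags`.
#' @export
toxicity_table <- function(model, ph, glucose_g_l, strain = "strain",
                           channel = "OD620", direction = c("od", "o2"),
                           acid_axis = "acetic_acid_mM", acid_max = NULL,
                           grid = 101L, min_effect = 0.05) {
  direction <- match.arg(direction)
  combos <- expand.grid(ph = ph, glucose_g_l = glucose_g_l,
                        KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    fx <- list(ph = combos$ph[i], glucose_g_l = combos$glucose_g_l[i])
    fx <- fx[names(fx) %in% model$axes]
    dr <- dose_response(model, fixed = fx, acid_axis = acid_axis,
                        acid_max = acid_max, grid = grid)
    resp <- dr$response
    flag <- ""
    if (direction == "o2") {
      resp <- max(resp) - resp
      flag <- "o2_reflected"
    }
    e <- ec50(dr$acid_mM, resp, min_effect = min_effect)
    data.frame(strain = strain, channel = channel,
               ph = combos$ph[i], glucose_g_l = combos$glucose_g_l[i],
               ec50_mM = e$ec50,
               toxicity_integral = curve_integral(dr$acid_mM, resp),
               flags = trimws(paste(flag, if (e$flag != "ok") e$flag else "")),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$relative_viability <- relative_viability(out$toxicity_integral,
                                               out$strain, out$channel)
  rownames(out) <- NULL
  out[, c("strain", "channel", "ph", "glucose_g_l", "ec50_mM",
          "toxicity_integral", "relative_viability", "flags")]
}
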