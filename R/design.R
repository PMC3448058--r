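#' Sequential maximin space-filling design
#'
#' Covers a multifactor parameter space with measurement points by greedy
#' maximin selection: a Latin-hypercube candidate pool is drawn in the
#' transformed unit hypercube, one start point is picked uniformly from the
#' pool, and each subsequent point is the candidate maximizing the minimum
#' Euclidean distance (in transformed coordinates) to the points already
#' selected. Distances are Euclidean in transformed coordinates, so the axis
#' scaling chosen in the [factor_spec()]s (log axes for concentrations)
#' already encodes the assumed sensitivity structure.
#'
#' Ties in the maximin criterion are broken by the lowest candidate index,
#' and the candidate pool is regenerated from `seed` on every call, so the
#' design is fully deterministic given `(factors, n_points, candidate_pool,
#' seed)`.
#'
#' @param factors List of [factor_spec()] objects (the design dimensions).
#' @param n_points Number of conditions to select (e.g. 48 per strain).
#' @param candidate_pool Size of the Latin-hypercube candidate pool;
#'   must be at least `n_points`.
#' @param seed Integer seed fixing pool and start point.
#' @param strains Optional character vector; the same design is replicated
#'   once per strain with a `strain` column added.
#' @return A `data.frame` with one column per factor in natural units (plus
#'   `strain` if requested), carrying the transformed coordinates in the
#'   `"coords"` attribute.
#' @examples
#' d <- space_filling_design(default_factors(), n_points = 48, seed = 1)
#' nrow(d)
#' @export
space_filling_design <- function(factors, n_points, candidate_pool = 1000L,
                                 seed = 1L, strains = NULL) {
  if (length(factors) == 0L)
    stop("empty factor list", call. = FALSE)
  if (!all(vapply(factors, inherits, logical(1), "factor_spec")))
    stop("'factors' must be a list of factor_spec objects", call. = FALSE)
  stopifnot(n_points >= 1L, candidate_pool >= n_points)
  d <- length(factors)
  set.seed(as.integer(seed))
  cand <- lhs::randomLHS(as.integer(candidate_pool), d)
  first <- sample.int(nrow(cand), 1L)
  sel <- maximin_select(cand, as.integer(n_points), first)
  coords <- cand[sel, , drop = FALSE]
  out <- as.data.frame(lapply(seq_len(d), function(j)
    inverse_axis(coords[, j], factors[[j]])))
  names(out) <- vapply(factors, `[[`, character(1), "name")
  if (!is.null(strains)) {
    out <- out[rep(seq_len(nrow(out)), times = length(strains)), , drop = FALSE]
    out$strain <- rep(strains, each = n_points)
    rownames(out) <- NULL
    coords <- coords[rep(seq_len(n_points), times = length(strains)), ,
                     drop = FALSE]
  }
  attr(out, "coords") <- coords
  attr(out, "factors") <- factors
  out
}

# Greedy maximin over a fixed candidate matrix: returns selected row indices.
# Ties broken toward the lowest candidate index (which.max semantics).
maximin_select <- function(cand, n_points, first) {
  n <- nrow(cand)
  sel <- integer(n_points)
  sel[1L] <- first
  # running minimum squared distance of every candidate to the selected set
  mind <- rowSums(sweep(cand, 2L, cand[first, ], "-")^2)
  mind[first] <- -Inf
  if (n_points > 1L) for (k in 2L:n_points) {
    nxt <- which.max(mind)
    sel[k] <- nxt
    mind <- pmin(mind, rowSums(sweep(cand, 2L, cand[nxt, ], "-")^2))
    mind[nxt] <- -Inf
  }
  sel
}

#' Monotone interpolant between two calibrated quantities
#'
#' Fits a shape-preserving monotone piecewise-cubic interpolant (Fritsch and
#' Carlson's method) through calibration pairs, together with its numerical
#' inverse. Used both for the buffer-fraction-to-pH conversion of the
#' two-buffer pH control system and for the pHluorin fluorescence-ratio
#' calibration. Unlike a generic cubic spline, the monotone interpolant
#' cannot overshoot between knots, so it is invertible wherever the
#' calibration data are strictly monotone.
#'
#' @param x Strictly increasing knot positions (e.g. buffer fractions in
#'   \eqn{[0,1]}).
#' @param y Strictly monotone responses at the knots (e.g. measured pH).
#' @return Object of class `"monotone_interpolant"`: a list with `fun`
#'   (forward map), `inv` (inverse map), and the knot table.
#' @export
monotone_interpolant <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(x) < 3L)
    stop("need at least 3 calibration pairs", call. = FALSE)
  if (any(diff(x) <= 0))
    stop("knot positions must be strictly increasing", call. = FALSE)
  dy <- diff(y)
  if (!(all(dy > 0) || all(dy < 0)))
    stop("calibration responses must be strictly monotone", call. = FALSE)
  increasing <- all(dy > 0)
  ys <- if (increasing) y else -y
  f <- stats::splinefun(x, ys, method = "monoH.FC")
  fun <- function(q) {
    if (any(q < min(x) - 1e-12 | q > max(x) + 1e-12, na.rm = TRUE))
      stop("query outside calibrated range [", min(x), ", ", max(x), "]",
           call. = FALSE)
    v <- f(pmin(pmax(q, min(x)), max(x)))
    if (increasing) v else -v
  }
  inv <- function(target) {
    lo <- min(y); hi <- max(y)
    if (any(target < lo - 1e-12 | target > hi + 1e-12, na.rm = TRUE))
      stop("query outside calibrated range [", lo, ", ", hi, "]",
           call. = FALSE)
    tgt <- if (increasing) target else -target
    tgt <- pmin(pmax(tgt, min(ys)), max(ys))
    vapply(tgt, function(ti) {
      if (ti <= ys[1L]) return(x[1L])
      if (ti >= ys[length(ys)]) return(x[length(x)])
      stats::uniroot(function(u) f(u) - ti, range(x),
                     tol = .Machine$double.eps^0.75)$root
    }, numeric(1))
  }
  structure(list(fun = fun, inv = inv, x = x, y = y, increasing = increasing),
            class = "monotone_interpolant")
}

#' @export
print.monotone_interpolant <- function(x, ...) {
  cat(sprintf("monotone %s interpolant through %d knots, x in [%g, %g]\n",
              if (x$increasing) "increasing" else "decreasing",
              length(x$x), min(x$x), max(x$x)))
  invisible(x)
}

#' Buffer-fraction to pH conversion
#'
#' The medium pH is set by mixing two citrate/phosphate buffers adjusted to
#' different pH values; a monotone spline through a measured titration table
#' converts between the mixing fraction of the high-pH buffer and the
#' resulting pH, in both directions.
#'
#' @param fractions Mixing fractions of the high-pH buffer, strictly
#'   increasing in \eqn{[0,1]}.
#' @param ph_values Measured pH at each fraction, strictly monotone.
#' @return A `"monotone_interpolant"`; `$fun(fraction)` gives pH,
#'   `$inv(ph)` gives the fraction.
#' @export
buffer_spline <- function(fractions, ph_values) {
  if (any(fractions < 0 | fractions > 1))
    stop("buffer fractions must lie in [0, 1]", call. = FALSE)
  monotone_interpolant(fractions, ph_values)
}
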