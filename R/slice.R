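#' Extract a 1D or 2D slice of a response surface
#'
#' High-dimensional response surfaces are explored through low-dimensional
#' slices: one or two factors vary over a regular grid in transformed
#' coordinates while the remaining factors are pinned at fixed values. Axis
#' labels are returned in natural units (back-transformed), so a log-scaled
#' concentration axis yields a log-spaced natural grid.
#'
#' @param model A fitted [gp_rsm()] model.
#' @param fixed Named list/vector pinning every factor not in `free` to a
#'   value in natural units.
#' @param free Character vector of one or two factor names to vary.
#' @param grid Grid resolution per free axis (default 41); at least 2.
#' @return `data.frame` of class `"gp_slice"` with one column per free axis
#'   (natural units), plus `mean` and `sd`; fixed values stored in the
#'   `"fixed"` attribute.
#' @examples
#' \donttest{
#' set.seed(1)
#' d <- expand.grid(x = seq(0, 1, len = 6), z = seq(0, 1, len = 6))
#' d$y <- sin(2 * pi * d$x) + d$z
#' fit <- gp_rsm(y ~ x + z, d)
#' s <- slice_surface(fit, fixed = list(z = 0.5), free = "x", grid = 21)
#' }
#' @export
slice_surface <- function(model, fixed = list(), free, grid = 41L) {
  stopifnot(inherits(model, "gp_rsm"))
  grid <- as.integer(grid)
  if (grid < 2L) stop("'grid' must be at least 2 per free axis", call. = FALSE)
  axes <- model$axes
  if (!all(free %in% axes))
    stop("unknown axis name(s): ",
         paste(setdiff(free, axes), collapse = ", "), call. = FALSE)
  if (length(free) < 1L || length(free) > 2L)
    stop("'free' must name one or two axes", call. = FALSE)
  pinned <- setdiff(axes, free)
  if (!all(pinned %in% names(fixed)))
    stop("missing fixed values for: ",
         paste(setdiff(pinned, names(fixed)), collapse = ", "), call. = FALSE)
  spec_of <- function(a) model$factors[[match(a, axes)]]
  # regular grid in transformed coordinates, back-transformed for labels
  tgrids <- lapply(free, function(a) seq(0, 1, length.out = grid))
  tq <- if (length(free) == 1L) {
    matrix(tgrids[[1L]], ncol = 1L)
  } else {
    as.matrix(expand.grid(tgrids[[1L]], tgrids[[2L]]))
  }
  Q <- matrix(NA_real_, nrow(tq), length(axes))
  for (j in seq_along(axes)) {
    a <- axes[j]
    if (a %in% free) {
      Q[, j] <- tq[, match(a, free)]
    } else {
      Q[, j] <- transform_axis(as.numeric(fixed[[a]]), spec_of(a))
    }
  }
  pr <- predict(model, Q, se.fit = TRUE, transformed = TRUE)
  out <- as.data.frame(lapply(seq_along(free), function(k)
    inverse_axis(tq[, k], spec_of(free[k]))))
  names(out) <- free
  out$mean <- pr$mean
  out$sd <- pr$sd
  attr(out, "fixed") <- fixed[pinned]
  attr(out, "response") <- model$response
  class(out) <- c("gp_slice", "data.frame")
  out
}

#' Plot a response-surface slice
#'
#' 1D slices are drawn as the predictive mean with a +/- 2 sd band; 2D
#' slices as a filled image with contour lines.
#'
#' @param x A fitted [gp_rsm()] model.
#' @param fixed,free,grid Passed to [slice_surface()]; by default the first
#'   axis is free and the others are pinned at their training medians.
#' @param ... Further graphical parameters.
#' @export
plot.gp_rsm <- function(x, fixed = NULL, free = NULL, grid = 41L, ...) {
  axes <- x$axes
  if (is.null(free)) free <- axes[seq_len(min(2L, length(axes)))]
  if (is.null(fixed)) {
    pinned <- setdiff(axes, free)
    fixed <- lapply(pinned, function(a) {
      j <- match(a, axes)
      stats::median(inverse_axis(x$X[, j], x$factors[[j]]))
    })
    names(fixed) <- pinned
  }
  s <- slice_surface(x, fixed = fixed, free = free, grid = grid)
  plot(s, ...)
  invisible(s)
}

#' @export
plot.gp_slice <- function(x, ...) {
  free <- setdiff(names(x), c("mean", "sd"))
  resp <- attr(x, "response")
  if (length(free) == 1L) {
    ax <- x[[free]]
    graphics::plot(ax, x$mean, type = "n",
                   ylim = range(c(x$mean - 2 * x$sd, x$mean + 2 * x$sd)),
                   xlab = free, ylab = resp, ...)
    graphics::polygon(c(ax, rev(ax)),
                      c(x$mean - 2 * x$sd, rev(x$mean + 2 * x$sd)),
                      col = grDevices::adjustcolor("steelblue", 0.3),
                      border = NA)
    graphics::lines(ax, x$mean, lwd = 2, col = "steelblue4")
  } else {
    u <- sort(unique(x[[free[1L]]]))
    v <- sort(unique(x[[free[2L]]]))
    z <- matrix(x$mean[order(x[[free[2L]]], x[[free[1L]]])],
                length(u), length(v))
    graphics::image(u, v, z, xlab = free[1L], ylab = free[2L],
                    col = grDevices::hcl.colors(50, "viridis"),
                    main = resp, ...)
    graphics::contour(u, v, z, add = TRUE, col = "white")
  }
  invisible(x)
}
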