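#' Gaussian ("squared-exponential") covariance with nugget
#'
#' The stationary covariance underlying the response-surface model:
#' \deqn{k(x_i, x_j) = \sigma_f^2 \exp\!\Big(-\tfrac12 \sum_k
#'   \big((x_{ik} - x_{jk})/l_k\big)^2\Big) + \sigma_n^2 \,\delta_{ij},}
#' where `sigma_f` sets the strength of correlation between measurements at
#' similar parameter combinations, the per-dimension length scales `l_k` set
#' its range along each (transformed) axis, and the nugget `sigma_n` is the
#' measurement-noise standard deviation added on the diagonal only.
#'
#' @param xi,xj Numeric location vectors of equal length (transformed
#'   coordinates).
#' @param sigma_f Signal standard deviation (> 0).
#' @param lengthscales Per-dimension length scales (> 0); recycled if scalar.
#' @param sigma_n Noise standard deviation (>= 0), default 0.
#' @param same_index `TRUE` when `xi` and `xj` are the same observation, so
#'   that the nugget applies.
#' @return The covariance value.
#' @examples
#' gp_covariance(c(0, 0), c(0, 0), sigma_f = 1, lengthscales = 1,
#'               sigma_n = 0.5, same_index = TRUE) # 1.25
#' @export
gp_covariance <- function(xi, xj, sigma_f, lengthscales, sigma_n = 0,
                          same_index = FALSE) {
  if (length(xi) != length(xj))
    stop("location dimension mismatch", call. = FALSE)
  stopifnot(sigma_f > 0, all(lengthscales > 0), sigma_n >= 0)
  ls <- rep_len(lengthscales, length(xi))
  sigma_f^2 * exp(-0.5 * sum(((xi - xj) / ls)^2)) +
    if (isTRUE(same_index)) sigma_n^2 else 0
}

# Correlation matrix exp(-1/2 sum((dx/l)^2)) between rows of X1 and X2.
gp_corr <- function(X1, X2, lengthscales) {
  d <- ncol(X1)
  ls <- rep_len(lengthscales, d)
  D2 <- matrix(0, nrow(X1), nrow(X2))
  for (k in seq_len(d)) {
    D2 <- D2 + outer(X1[, k] / ls[k], X2[, k] / ls[k], "-")^2
  }
  exp(-0.5 * D2)
}

# GCV score for noise-to-signal ratio lambda, given the eigen-decomposition
# of the correlation matrix R = U diag(ev) U' and z = U' (y - mean).
# The smoother A(lambda) = R (R + lambda I)^-1 maps centred responses to
# fitted means, so in the eigenbasis 1 - a_i = lambda / (ev_i + lambda).
gp_gcv_score <- function(log_lambda, ev, z2, n) {
  lambda <- exp(log_lambda)
  w <- lambda / (ev + lambda)
  num <- n * sum(w^2 * z2)
  den <- sum(w)^2
  num / den
}

# Inner loop of the fit: for fixed lengthscales choose lambda = sigma_n^2 /
# sigma_f^2 by GCV (log-grid search then golden-section refinement), then set
# sigma_f^2 by the profile likelihood given lambda.
gp_inner_fit <- function(Xs, yc, lengthscales,
                         lambda_range = c(1e-8, 1e2), n_grid = 25L) {
  n <- length(yc)
  R <- gp_corr(Xs, Xs, lengthscales)
  eg <- eigen(R, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  z <- drop(crossprod(eg$vectors, yc))
  z2 <- z^2
  grid <- seq(log(lambda_range[1L]), log(lambda_range[2L]),
              length.out = n_grid)
  scores <- vapply(grid, gp_gcv_score, numeric(1), ev = ev, z2 = z2, n = n)
  i <- which.min(scores)
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, n_grid)]
  opt <- stats::optimize(gp_gcv_score, c(lo, hi), ev = ev, z2 = z2, n = n,
                         tol = 1e-6)
  if (opt$objective < scores[i]) {
    log_lambda <- opt$minimum
    gcv <- opt$objective
  } else {
    log_lambda <- grid[i]
    gcv <- scores[i]
  }
  lambda <- exp(log_lambda)
  # profile maximum-likelihood estimate of sigma_f^2 given lambda:
  # sigma_f^2 = y' (R + lambda I)^-1 y / n in the eigenbasis
  sigma_f2 <- sum(z2 / (ev + lambda)) / n
  list(lambda = lambda, gcv = gcv, sigma_f2 = sigma_f2,
       sigma_n2 = lambda * sigma_f2)
}

# Profile negative log marginal likelihood for fixed lengthscales, with
# sigma_f^2 and lambda profiled out (lambda by inner 1D optimization).
# Unlike the GCV score this keeps the log-determinant term, which breaks
# the nugget-lengthscale ridge and identifies the correlation range.
gp_profile_nll <- function(Xs, yc, lengthscales,
                           lambda_range = c(1e-8, 1e2)) {
  n <- length(yc)
  R <- gp_corr(Xs, Xs, lengthscales)
  eg <- eigen(R, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  z2 <- drop(crossprod(eg$vectors, yc))^2
  f <- function(log_lambda) {
    lambda <- exp(log_lambda)
    s2 <- sum(z2 / (ev + lambda)) / n
    0.5 * (n * log(s2) + sum(log(ev + lambda)))
  }
  stats::optimize(f, log(lambda_range), tol = 1e-6)$objective
}

#' Fit a Gaussian-process response-surface model
#'
#' Fits a Kriging response surface of a scalar response (growth rate, OD
#' integral, oxygen integral, ...) over the transformed experimental factor
#' space. The model treats observations as draws from a Gaussian process
#' with constant prior mean (set to the training-response mean), the
#' anisotropic Gaussian covariance of [gp_covariance()], and a nugget for
#' measurement noise.
#'
#' Hyperparameters are estimated in two nested loops. For candidate length
#' scales, the noise-to-signal ratio \eqn{\lambda = \sigma_n^2/\sigma_f^2}
#' minimizes the generalized cross-validation score
#' \deqn{GCV(\lambda) = n\,\lVert (I - A(\lambda))\,y \rVert^2 /
#'   \mathrm{tr}(I - A(\lambda))^2,}
#' with \eqn{A(\lambda)} the smoother matrix of the GP mean predictor
#' (searched on a 25-point log grid over \eqn{[10^{-8}, 10^{2}]} and refined
#' by golden section), and \eqn{\sigma_f^2} maximizes the profile likelihood
#' given \eqn{\lambda}. The outer loop runs Nelder-Mead over the
#' log-length-scales, one per model dimension, started at length scale 0.3
#' in every transformed dimension.
#'
#' Two outer objectives are available. The default, `objective = "ml"`,
#' minimizes the profile negative log marginal likelihood (with
#' \eqn{\sigma_f^2} and \eqn{\lambda} profiled out): the log-determinant
#' term breaks the nugget-lengthscale ridge along which the GCV score is
#' nearly flat, so correlation ranges are actually identified.
#' `objective = "gcv"` instead uses the GCV score itself for the outer loop
#' (the joint cross-validation behavior); predictions along the ridge are
#' nearly identical, but the fitted length scales are then only weakly
#' determined. In both cases the returned model's noise level is the GCV
#' choice at the selected length scales.
#'
#' @param formula Model formula, response on the left and the design factors
#'   on the right, e.g. `od_integral ~ glucose_g_l + ph + acetic_acid_mM`.
#' @param data `data.frame` holding the response and factor columns in
#'   natural units.
#' @param factors Optional list of [factor_spec()]s matching the right-hand
#'   side; by default linear specs spanning each column's observed range.
#' @param optimize If `TRUE` (default) run the Nelder-Mead length-scale
#'   optimization; if `FALSE` keep `lengthscales` fixed and only estimate
#'   the noise level by GCV.
#' @param objective Outer-loop objective: `"ml"` (profile marginal
#'   likelihood, default) or `"gcv"` (GCV score).
#' @param lengthscales Starting (or fixed) length scales in transformed
#'   coordinates; default 0.3 in every dimension.
#' @param seed Integer seed controlling the optimizer start perturbation.
#' @param control List of optimizer settings: `maxit` (default 200) and
#'   `abstol` (default 1e-6) for the Nelder-Mead loop, `jitter` (default
#'   1e-10) relative diagonal jitter used when the fitted nugget vanishes.
#' @return Object of class `"gp_rsm"` with components `X` (transformed
#'   training locations), `y`, `sigma_f`, `lengthscales`, `sigma_n`,
#'   `mean_level`, `factors`, `gcv`, `converged`, and the Cholesky solve
#'   cache used by [predict.gp_rsm()].
#' @seealso [predict.gp_rsm()], [slice_surface()], [dose_response()]
#' @examples
#' set.seed(1)
#' d <- data.frame(x = runif(30))
#' d$y <- sin(2 * pi * d$x) + rnorm(30, sd = 0.1)
#' fit <- gp_rsm(y ~ x, d)
#' predict(fit, data.frame(x = 0.5))
#' @export
gp_rsm <- function(formula, data, factors = NULL, optimize = TRUE,
                   objective = c("ml", "gcv"), lengthscales = NULL,
                   seed = 1L, control = list()) {
  objective <- match.arg(objective)
  stopifnot(inherits(formula, "formula"), is.data.frame(data))
  ctl <- modify_defaults(list(maxit = 200L, abstol = 1e-6, jitter = 1e-10),
                         control)
  vars <- all.vars(formula)
  response <- vars[1L]
  axes <- vars[-1L]
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols))
    stop("columns not found in 'data': ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  y <- as.numeric(data[[response]])
  if (any(!is.finite(y)))
    stop("non-finite response values", call. = FALSE)
  d <- length(axes)
  if (d == 0L) stop("formula needs at least one factor", call. = FALSE)
  if (is.null(factors)) {
    factors <- lapply(axes, function(a)
      factor_spec(a, min(data[[a]]), max(data[[a]]), scale = "linear"))
  }
  fnames <- vapply(factors, `[[`, character(1), "name")
  if (!setequal(fnames, axes) || length(factors) != d)
    stop("'factors' must match the formula's right-hand side", call. = FALSE)
  factors <- factors[match(axes, fnames)]
  Xs <- vapply(seq_len(d), function(j)
    transform_axis(data[[axes[j]]], factors[[j]]), numeric(nrow(data)))
  Xs <- matrix(Xs, ncol = d)
  n <- nrow(Xs)
  mean_level <- mean(y)
  yc <- y - mean_level

  if (is.null(lengthscales)) lengthscales <- rep(0.3, d)
  lengthscales <- rep_len(lengthscales, d)
  stopifnot(all(lengthscales > 0))

  if (stats::sd(y) == 0) {
    # degenerate flat surface: predictions are the constant mean
    fit <- list(lambda = 1e-8, gcv = 0, sigma_f2 = 1e-12, sigma_n2 = 0)
    model <- build_gp_model(Xs, y, factors, axes, response, lengthscales,
                            fit, mean_level, ctl, converged = TRUE)
    return(model)
  }

  converged <- TRUE
  if (optimize && n >= 5L) {
    set.seed(as.integer(seed))
    start <- log(lengthscales)
    obj <- function(log_ls) {
      ls <- exp(pmin(pmax(log_ls, log(1e-3)), log(1e3)))
      if (objective == "ml") gp_profile_nll(Xs, yc, ls)
      else gp_inner_fit(Xs, yc, ls)$gcv
    }
    if (d == 1L) {
      opt <- stats::optimize(obj, c(log(1e-3), log(1e3)), tol = 1e-6)
      par <- opt$minimum
    } else {
      fit_nm <- stats::optim(start, obj, method = "Nelder-Mead",
                             control = list(maxit = ctl$maxit,
                                            abstol = ctl$abstol))
      if (fit_nm$convergence != 0) {
        warning("length-scale optimization did not converge; ",
                "returning best parameters seen", call. = FALSE)
        converged <- FALSE
      }
      par <- fit_nm$par
    }
    lengthscales <- exp(pmin(pmax(par, log(1e-3)), log(1e3)))
  }
  fit <- gp_inner_fit(Xs, yc, lengthscales)
  build_gp_model(Xs, y, factors, axes, response, lengthscales, fit,
                 mean_level, ctl, converged)
}

#' Construct a response-surface model with given hyperparameters
#'
#' Builds a `"gp_rsm"` object directly from training data and fully
#' specified hyperparameters, bypassing estimation — useful for
#' cross-checking predictions against closed forms, or for reloading a
#' previously fitted model.
#'
#' @param X Matrix of training locations in transformed \eqn{[0,1]}
#'   coordinates (n x d).
#' @param y Training responses.
#' @param sigma_f Signal standard deviation (> 0).
#' @param lengthscales Per-dimension length scales (> 0).
#' @param sigma_n Noise standard deviation (>= 0).
#' @param mean_level Constant prior mean; defaults to `mean(y)`.
#' @param factors Optional list of [factor_spec()]s (defaults to linear
#'   unit axes named `x1...xd`).
#' @param response Response label.
#' @param jitter Relative diagonal jitter applied when `sigma_n` is 0
#'   (default 1e-10); set to 0 to demand an exactly invertible covariance.
#' @return A `"gp_rsm"` model.
#' @export
gp_model <- function(X, y, sigma_f, lengthscales, sigma_n = 0,
                     mean_level = mean(y), factors = NULL,
                     response = "response", jitter = 1e-10) {
  X <- as.matrix(X)
  d <- ncol(X)
  stopifnot(nrow(X) == length(y), sigma_f > 0, all(lengthscales > 0),
            sigma_n >= 0)
  if (is.null(factors))
    factors <- lapply(seq_len(d), function(j)
      factor_spec(paste0("x", j), 0, 1, "linear"))
  axes <- vapply(factors, `[[`, character(1), "name")
  fit <- list(sigma_f2 = sigma_f^2, sigma_n2 = sigma_n^2,
              lambda = (sigma_n / sigma_f)^2, gcv = NA_real_)
  build_gp_model(X, y, factors, axes, response,
                 rep_len(lengthscales, d), fit, mean_level,
                 list(jitter = jitter), converged = TRUE)
}

# Assemble the fitted model object, factorizing K once for predictions.
build_gp_model <- function(Xs, y, factors, axes, response, lengthscales,
                           fit, mean_level, ctl, converged) {
  n <- nrow(Xs)
  sigma_f2 <- max(fit$sigma_f2, 1e-12)
  sigma_n2 <- fit$sigma_n2
  K0 <- sigma_f2 * gp_corr(Xs, Xs, lengthscales)
  diag(K0) <- diag(K0) + sigma_n2
  # escalate diagonal jitter only as far as the factorization requires,
  # so a vanishing nugget still interpolates to near machine precision
  jitters <- c(0, 10^seq(-14, log10(max(ctl$jitter, 1e-14))))
  if (ctl$jitter == 0) jitters <- 0
  L <- NULL
  for (j in jitters) {
    K <- K0
    diag(K) <- diag(K) + j * sigma_f2
    L <- tryCatch(chol(K), error = function(e) NULL)
    if (!is.null(L)) break
  }
  if (is.null(L))
    stop("covariance matrix is numerically singular (duplicated training ",
         "points with a zero nugget?); supply a positive noise level",
         call. = FALSE)
  alpha <- backsolve(L, forwardsolve(t(L), y - mean_level))
  structure(list(
    X = Xs, y = y, factors = factors, axes = axes, response = response,
    sigma_f = sqrt(sigma_f2), lengthscales = lengthscales,
    sigma_n = sqrt(sigma_n2), mean_level = mean_level,
    gcv = fit$gcv, lambda = fit$lambda, converged = converged,
    chol_K = L, alpha = alpha, jitter = ctl$jitter
  ), class = "gp_rsm")
}

#' Predict from a fitted response-surface model
#'
#' Conditional-mean prediction at new parameter combinations, with the
#' predictive standard deviation: `mean = mu + k*' K^-1 (y - mu)` and
#' `sd^2 = sigma_f^2 - k*' K^-1 k*` (clamped at zero), where `K` carries the
#' nugget on its diagonal and the cross-covariance `k*` does not. Far from
#' all training data the prediction reverts to the prior mean with
#' standard deviation `sigma_f`.
#'
#' @param object A fitted [gp_rsm()] model.
#' @param newdata `data.frame` with the model's factor columns in natural
#'   units (or a numeric matrix already in transformed coordinates, with
#'   `transformed = TRUE`).
#' @param se.fit Return predictive standard deviations (default `TRUE`).
#' @param transformed Set `TRUE` when `newdata` is already a matrix of
#'   transformed coordinates.
#' @param ... Unused.
#' @return `data.frame` with columns `mean` and (if requested) `sd`.
#' @export
predict.gp_rsm <- function(object, newdata, se.fit = TRUE,
                           transformed = FALSE, ...) {
  d <- length(object$axes)
  if (isTRUE(transformed)) {
    Q <- as.matrix(newdata)
  } else {
    if (!all(object$axes %in% names(newdata)))
      stop("'newdata' must contain columns: ",
           paste(object$axes, collapse = ", "), call. = FALSE)
    Q <- vapply(seq_len(d), function(j)
      transform_axis(as.numeric(newdata[[object$axes[j]]]),
                     object$factors[[j]]),
      numeric(NROW(newdata)))
    Q <- matrix(Q, ncol = d)
  }
  if (ncol(Q) != d) stop("query dimension mismatch", call. = FALSE)
  ks <- object$sigma_f^2 * gp_corr(Q, object$X, object$lengthscales)
  mu <- object$mean_level + drop(ks %*% object$alpha)
  if (!se.fit) return(data.frame(mean = mu))
  L <- object$chol_K
  v <- forwardsolve(t(L), t(ks))
  var <- pmax(object$sigma_f^2 - colSums(v^2), 0)
  data.frame(mean = mu, sd = sqrt(var))
}

#' @export
fitted.gp_rsm <- function(object, ...) {
  predict(object, object$X, se.fit = FALSE, transformed = TRUE)$mean
}

#' @export
residuals.gp_rsm <- function(object, ...) {
  object$y - fitted(object)
}

#' @export
coef.gp_rsm <- function(object, ...) {
  c(sigma_f = object$sigma_f,
    stats::setNames(object$lengthscales,
                    paste0("lengthscale_", object$axes)),
    sigma_n = object$sigma_n, mean_level = object$mean_level)
}

#' @export
print.gp_rsm <- function(x, ...) {
  cat("Gaussian-process response surface (Kriging)\n")
  cat(sprintf("  response: %s on %d observations, %d factor(s)\n",
              x$response, length(x$y), length(x$axes)))
  cat(sprintf("  sigma_f = %.4g, sigma_n = %.4g (GCV lambda = %.3g)\n",
              x$sigma_f, x$sigma_n, x$lambda))
  cat("  length scales (transformed coords):\n")
  for (j in seq_along(x$axes))
    cat(sprintf("    %-16s %.4g\n", x$axes[j], x$lengthscales[j]))
  if (!x$converged) cat("  note: length-scale optimization did not converge\n")
  invisible(x)
}

#' @export
summary.gp_rsm <- function(object, ...) {
  res <- residuals(object)
  structure(list(model = object, residual_sd = stats::sd(res),
                 residual_range = range(res),
                 response_range = range(object$y)),
            class = "summary.gp_rsm")
}

#' @export
print.summary.gp_rsm <- function(x, ...) {
  print(x$model)
  cat(sprintf("  training residual sd: %.4g (response range %.4g .. %.4g)\n",
              x$residual_sd, x$response_range[1], x$response_range[2]))
  invisible(x)
}

#' Simulate response draws from the fitted surface
#'
#' Draws joint samples from the posterior Gaussian process at a set of
#' locations (the training locations by default), reflecting both the
#' fitted surface and its remaining uncertainty.
#'
#' @param object A fitted [gp_rsm()] model.
#' @param nsim Number of draws.
#' @param seed Optional integer seed.
#' @param newdata Locations at which to simulate (natural units); defaults
#'   to the training locations.
#' @param ... Unused.
#' @return Matrix with one column per draw.
#' @export
simulate.gp_rsm <- function(object, nsim = 1, seed = NULL, newdata = NULL,
                            ...) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(newdata)) {
    Q <- object$X
    transformed <- TRUE
  } else {
    Q <- newdata
    transformed <- FALSE
  }
  pr <- predict(object, Q, se.fit = TRUE, transformed = transformed)
  if (isTRUE(transformed)) Qm <- as.matrix(Q) else {
    d <- length(object$axes)
    Qm <- vapply(seq_len(d), function(j)
      transform_axis(as.numeric(newdata[[object$axes[j]]]),
                     object$factors[[j]]), numeric(NROW(newdata)))
    Qm <- matrix(Qm, ncol = d)
  }
  Kss <- object$sigma_f^2 * gp_corr(Qm, Qm, object$lengthscales)
  ks <- object$sigma_f^2 * gp_corr(Qm, object$X, object$lengthscales)
  L <- object$chol_K
  v <- forwardsolve(t(L), t(ks))
  Sig <- Kss - crossprod(v)
  Sig <- (Sig + t(Sig)) / 2
  diag(Sig) <- diag(Sig) + 1e-10 * object$sigma_f^2
  Ls <- chol(Sig)
  m <- nrow(Qm)
  pr$mean + t(Ls) %*% matrix(stats::rnorm(m * nsim), m, nsim)
}

# merge user control values over defaults
modify_defaults <- function(defaults, values) {
  stopifnot(is.list(values))
  defaults[names(values)] <- values
  defaults
}
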