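# Independent oracles used across the suite. These deliberately use naive,
# loop-based formulations so they share no code path with the package
# internals they check.

# pairwise trapezoid sum, one term per interval
trapezoid_oracle <- function(t, v) {
  s <- 0
  for (i in 2:length(t)) s <- s + 0.5 * (v[i] + v[i - 1]) * (t[i] - t[i - 1])
  s
}

# closed-form least-squares slope of log(v) vs t (hours) in one window
window_slope_oracle <- function(t_h, logv) {
  n <- length(t_h)
  sx <- sum(t_h); sy <- sum(logv)
  (n * sum(t_h * logv) - sx * sy) / (n * sum(t_h^2) - sx^2)
}

# dense build-K-and-solve GP predictor, element-by-element covariance
gp_oracle_predict <- function(X, y, Q, sigma_f, ls, sigma_n, mean_level,
                              jitter = 1e-10) {
  n <- nrow(X); m <- nrow(Q)
  K <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n)
    K[i, j] <- gp_covariance(X[i, ], X[j, ], sigma_f, ls, sigma_n, i == j)
  if (sigma_n^2 < jitter * sigma_f^2)
    diag(K) <- diag(K) + jitter * sigma_f^2
  ks <- matrix(0, m, n)
  for (i in 1:m) for (j in 1:n)
    ks[i, j] <- gp_covariance(Q[i, ], X[j, ], sigma_f, ls, 0, FALSE)
  Kinv <- solve(K)
  mu <- mean_level + drop(ks %*% Kinv %*% (y - mean_level))
  s2 <- pmax(sigma_f^2 - diag(ks %*% Kinv %*% t(ks)), 0)
  list(mean = mu, sd = sqrt(s2))
}

# draw a function from a 1D GP with Gaussian kernel plus iid noise
gp_draw_1d <- function(n, l, sigma_f = 1, sigma_n = 0, seed = 1) {
  set.seed(seed)
  x <- runif(n)
  K <- sigma_f^2 * exp(-0.5 * outer(x, x, "-")^2 / l^2)
  diag(K) <- diag(K) + 1e-10
  y <- drop(t(chol(K)) %*% rnorm(n)) + rnorm(n, 0, sigma_n)
  data.frame(x = x, y = y)
}

# noiseless simulated OD-integral dose-response by direct simulation
sim_od_integral <- function(glucose, ph, acid, strain = "wild-type",
                            params = sim_params(noise_sd = 0)) {
  g <- simulate_growth_curve(list(glucose_g_l = glucose, ph = ph,
                                  acetic_acid_mM = acid, strain = strain),
                             params, seed = 1)
  curve_integral(g$time_min / 60, g$value)
}

unit_factor <- function(name = "x") factor_spec(name, 0, 1, "linear")
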