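test_that("the Gaussian covariance matches its closed form", {
  expect_equal(gp_covariance(c(0, 0), c(0, 0), 1, 1, 0.5, TRUE), 1.25)
  # unit scaled distance
  expect_equal(gp_covariance(0, 1, 1, 1, 0), exp(-0.5))
  expect_equal(gp_covariance(c(0.3, 0.1), c(0.5, 0.4), 2, c(0.2, 0.3), 0),
               4 * exp(-0.5 * ((0.2 / 0.2)^2 + (0.3 / 0.3)^2)))
  # symmetry, bound, decay
  expect_equal(gp_covariance(0.2, 0.9, 1.3, 0.4, 0),
               gp_covariance(0.9, 0.2, 1.3, 0.4, 0))
  expect_lt(gp_covariance(0, 100 * 0.3, 1, 0.3, 0), 1e-10)
  expect_lte(gp_covariance(0.5, 0.5, 2, 1, 1, TRUE), 2^2 + 1^2)
  expect_error(gp_covariance(c(0, 0), 0, 1, 1), "dimension")
})

test_that("predictions obey one-point closed forms and prior reversion", {
  m <- gp_model(matrix(0.5), y = 2, sigma_f = 1, lengthscales = 0.3,
                sigma_n = 0, mean_level = 0)
  at_x0 <- predict(m, matrix(0.5), transformed = TRUE)
  expect_equal(at_x0$mean, 2, tolerance = 1e-6)
  expect_equal(at_x0$sd, 0, tolerance = 1e-4)
  far <- predict(m, matrix(50), transformed = TRUE)
  expect_equal(far$mean, 0, tolerance = 1e-10)
  expect_equal(far$sd, 1, tolerance = 1e-10)
  # nugget shrinks the training-point prediction toward the mean:
  # mean = mu + sigma_f^2/(sigma_f^2+sigma_n^2) (y - mu)
  for (sn in c(0.1, 0.5, 2)) {
    mn <- gp_model(matrix(0.5), y = 2, sigma_f = 1, lengthscales = 0.3,
                   sigma_n = sn, mean_level = 0)
    expect_equal(predict(mn, matrix(0.5), transformed = TRUE)$mean,
                 1 / (1 + sn^2) * 2, tolerance = 1e-12)
  }
})

test_that("predictions match the dense build-and-solve oracle", {
  set.seed(3)
  for (d in 1:3) {
    X <- matrix(runif(20 * d), 20, d)
    y <- sin(2 * pi * X[, 1]) + rnorm(20, 0, 0.1)
    ls <- runif(d, 0.2, 0.6)
    m <- gp_model(X, y, sigma_f = 1.3, lengthscales = ls, sigma_n = 0.15)
    Q <- matrix(runif(8 * d), 8, d)
    o <- gp_oracle_predict(X, y, Q, 1.3, ls, 0.15, mean(y))
    p <- predict(m, Q, transformed = TRUE)
    expect_lt(max(abs(p$mean - o$mean)) / diff(range(y)), 1e-8)
    expect_lt(max(abs(p$sd - o$sd)), 1e-8)
  }
})

test_that("shuffling training rows leaves predictions unchanged", {
  set.seed(9)
  X <- matrix(runif(40), 20, 2)
  y <- X[, 1]^2 + cos(3 * X[, 2])
  perm <- sample(20)
  m1 <- gp_model(X, y, 1, c(0.3, 0.3), 0.05)
  m2 <- gp_model(X[perm, ], y[perm], 1, c(0.3, 0.3), 0.05)
  Q <- matrix(runif(10), 5, 2)
  expect_lt(max(abs(predict(m1, Q, transformed = TRUE)$mean -
                      predict(m2, Q, transformed = TRUE)$mean)), 1e-12)
})

test_that("a vanishing nugget recovers interpolation of the training data", {
  set.seed(4)
  X <- matrix(runif(25), ncol = 1)
  y <- sin(3 * X[, 1])
  m <- gp_model(X, y, sigma_f = 1, lengthscales = 0.3, sigma_n = 1e-8)
  expect_lt(max(abs(predict(m, X, transformed = TRUE)$mean - y)), 1e-6)
})

test_that("fitting degenerates gracefully and self-validates on smooth data", {
  # constant response: flat surface at the mean
  dflat <- data.frame(x = seq(0, 1, length.out = 10), y = 2.5)
  mflat <- gp_rsm(y ~ x, dflat, factors = list(unit_factor()))
  expect_equal(predict(mflat, data.frame(x = c(0.1, 0.9)))$mean, c(2.5, 2.5))

  # noiseless two-bump surface: leave-one-out error well under 5% of range
  set.seed(21)
  x <- runif(40)
  f <- function(x) exp(-(x - 0.3)^2 / 0.02) + 0.7 * exp(-(x - 0.75)^2 / 0.01)
  y <- f(x)
  errs <- vapply(1:40, function(i) {
    fit <- gp_rsm(y ~ x, data.frame(x = x[-i], y = y[-i]),
                  factors = list(unit_factor()), seed = 1)
    predict(fit, data.frame(x = x[i]))$mean - y[i]
  }, numeric(1))
  expect_lt(sqrt(mean(errs^2)), 0.05 * diff(range(y)))
})

test_that("duplicated noise-free training points raise a conditioning error", {
  X <- matrix(c(0.5, 0.5, 0.7), ncol = 1)
  expect_error(gp_model(X, c(1, 2, 3), 1, 0.3, sigma_n = 0, jitter = 0),
               "nugget|singular")
  # the default jitter keeps the same data usable
  expect_s3_class(gp_model(X, c(1, 2, 3), 1, 0.3, sigma_n = 0.1), "gp_rsm")
})

test_that("model methods report coherent summaries", {
  set.seed(2)
  d <- data.frame(x = runif(25))
  d$y <- cos(2 * pi * d$x) + rnorm(25, 0, 0.05)
  fit <- gp_rsm(y ~ x, d, factors = list(unit_factor()), seed = 1)
  expect_s3_class(fit, "gp_rsm")
  co <- coef(fit)
  expect_named(co, c("sigma_f", "lengthscale_x", "sigma_n", "mean_level"))
  expect_equal(fitted(fit) + residuals(fit), d$y)
  expect_output(print(fit), "Kriging")
  expect_output(print(summary(fit)), "residual sd")
  sims <- simulate(fit, nsim = 3, seed = 7)
  expect_equal(dim(sims), c(25L, 3L))
  expect_identical(simulate(fit, 2, seed = 5), simulate(fit, 2, seed = 5))
})

test_that("surface slices agree with pointwise prediction and track fixed values", {
  set.seed(5)
  g <- expand.grid(ph = seq(3, 7, length.out = 7),
                   acid = seq(0, 100, length.out = 7))
  g$y <- 10 / (1 + (g$acid / 40)^2) + 0.5 * g$ph
  factors <- list(factor_spec("ph", 3, 7, "linear"),
                  factor_spec("acid", 0, 100, "linear"))
  fit <- gp_rsm(y ~ ph + acid, g, factors = factors, seed = 1)

  s <- slice_surface(fit, fixed = list(ph = 4), free = "acid", grid = 21)
  nd <- data.frame(ph = 4, acid = s$acid)
  expect_equal(s$mean, predict(fit, nd)$mean)

  s2 <- slice_surface(fit, fixed = list(), free = c("ph", "acid"), grid = 21)
  expect_equal(nrow(s2), 441)
  i <- sample(441, 20)
  expect_equal(s2$mean[i],
               predict(fit, s2[i, c("ph", "acid")])$mean)

  # pH-dependent surface: different fixed pH, different slice; same, same
  sA <- slice_surface(fit, fixed = list(ph = 3.2), free = "acid")
  sB <- slice_surface(fit, fixed = list(ph = 6.8), free = "acid")
  sA2 <- slice_surface(fit, fixed = list(ph = 3.2), free = "acid")
  expect_false(isTRUE(all.equal(sA$mean, sB$mean)))
  expect_identical(sA$mean, sA2$mean)
  expect_error(slice_surface(fit, fixed = list(ph = 4), free = "nope"),
               "unknown axis")
})

test_that("1D interpolating slice reproduces training responses on its grid", {
  x <- seq(0, 1, length.out = 11)
  y <- sin(2 * pi * x)
  m <- gp_model(matrix(x), y, sigma_f = 1, lengthscales = 0.25,
                sigma_n = 0, factors = list(unit_factor()))
  s <- slice_surface(m, fixed = list(), free = "x", grid = 11)
  expect_equal(s$mean, y, tolerance = 1e-5)
})
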