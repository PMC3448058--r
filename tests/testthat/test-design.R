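test_that("axis transforms map bounds to [0,1] and round-trip exactly", {
  lin <- factor_spec("acid", 0, 120, "linear")
  expect_equal(transform_axis(60, lin), 0.5)
  expect_equal(transform_axis(c(0, 120), lin), c(0, 1))

  lg <- factor_spec("acid", 0, 40, "log", offset = 1)
  expect_equal(transform_axis(0, lg), 0)
  expect_equal(transform_axis(40, lg), 1)

  set.seed(42)
  for (spec in list(lin, lg, factor_spec("ph", 2.5, 7, "linear"))) {
    v <- runif(100, spec$lower, spec$upper)
    back <- inverse_axis(transform_axis(v, spec), spec)
    expect_lt(max(abs(back - v)), 1e-12)
    expect_true(all(diff(transform_axis(sort(v), spec)) > 0))
  }
})

test_that("axis transforms reject out-of-range and degenerate input", {
  lin <- factor_spec("acid", 0, 120, "linear")
  expect_error(transform_axis(121, lin), "outside")
  expect_error(transform_axis(-1, lin), "outside")
  expect_error(factor_spec("bad", 5, 5, "linear"), "lower < upper")
  expect_error(factor_spec("bad", -2, 5, "log", offset = 1), "positive")
})

test_that("maximin selection picks the farthest candidate at every step", {
  # tiny hand-checkable pool: from 0 the farthest point is 1
  cand <- matrix(c(0, 0.5, 1), ncol = 1)
  sel <- acetox:::maximin_select(cand, 3L, first = 1L)
  expect_identical(sel, c(1L, 3L, 2L))

  # exhaustive oracle over a 200-candidate pool in 2D
  set.seed(7)
  cand <- matrix(runif(400), ncol = 2)
  sel <- acetox:::maximin_select(cand, 10L, first = 17L)
  chosen <- 17L
  for (k in 2:10) {
    mind <- sapply(seq_len(nrow(cand)), function(i) {
      if (i %in% chosen) return(-Inf)
      min(sqrt(rowSums((cand[chosen, , drop = FALSE] -
                          matrix(cand[i, ], length(chosen), 2,
                                 byrow = TRUE))^2)))
    })
    expect_identical(sel[k], which.max(mind))
    chosen <- c(chosen, sel[k])
  }
})

test_that("space-filling designs are deterministic, in-bounds and space-filling", {
  factors <- default_factors()
  d1 <- space_filling_design(factors, 48, seed = 5)
  d2 <- space_filling_design(factors, 48, seed = 5)
  expect_identical(attr(d1, "coords"), attr(d2, "coords"))
  expect_equal(nrow(d1), 48)
  expect_equal(nrow(unique(d1)), 48)
  for (f in factors) {
    expect_true(all(d1[[f$name]] >= f$lower - 1e-9 &
                      d1[[f$name]] <= f$upper + 1e-9))
  }
  # different seed, different design
  d3 <- space_filling_design(factors, 48, seed = 6)
  expect_false(identical(attr(d1, "coords"), attr(d3, "coords")))

  # per-strain replication of the same conditions
  ds <- space_filling_design(factors, 12, seed = 1,
                             strains = c("wild-type", "hap4"))
  expect_equal(nrow(ds), 24)
  expect_equal(ds[1:12, 1:3], ds[13:24, 1:3], ignore_attr = TRUE)

  # 1D coverage: largest gap of sorted coordinates under 3/n
  for (seed in 1:3) {
    dc <- space_filling_design(list(unit_factor()), 24, 1000, seed = seed)
    gaps <- diff(sort(attr(dc, "coords")[, 1]))
    expect_lt(max(gaps), 3 / 24)
  }
  expect_error(space_filling_design(list(), 5), "empty factor")
})

test_that("buffer spline interpolates knots, stays monotone and inverts", {
  # synthetic titration of a citrate/phosphate two-buffer system
  fr <- seq(0, 1, length.out = 9)
  ph <- 2.8 + 4.4 / (1 + exp(-6 * (fr - 0.5)))
  bs <- buffer_spline(fr, ph)
  expect_equal(bs$fun(fr), ph)
  expect_equal(bs$fun(0), ph[1])
  # monotone on a dense grid, no overshoot between knots
  g <- seq(0, 1, length.out = 500)
  expect_true(all(diff(bs$fun(g)) >= 0))
  # fraction -> pH -> fraction round trip
  q <- seq(0.02, 0.98, length.out = 50)
  expect_lt(max(abs(bs$inv(bs$fun(q)) - q)), 1e-8)
  expect_error(buffer_spline(fr, c(ph[1:4], ph[3], ph[6:9])), "monotone")
  expect_error(bs$inv(10), "outside")
})
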