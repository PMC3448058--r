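test_that("ec50 finds the half-effect dose by midpoint crossing", {
  # steep symmetric inhibition curve centred at 50 mM
  cgrid <- seq(0, 200, length.out = 101)
  e <- ec50(cgrid, 1 / (1 + (cgrid / 50)^4))
  expect_lt(abs(e$ec50 - 50), 0.5)
  expect_identical(e$flag, "ok")
  # straight line from 2 to 0 crosses its midpoint at the centre
  expect_equal(ec50(seq(0, 100), seq(2, 0, length.out = 101))$ec50, 50)
  # interpolation between coarse grid points: 0.75 -> 0 over [40, 80]
  # crosses the 0.5 level a third of the way in
  expect_equal(ec50(c(0, 40, 80), c(1, 0.75, 0))$ec50, 40 + 40 / 3)
})

test_that("ec50 is affine-invariant and flags degenerate curves", {
  cgrid <- seq(0, 120, length.out = 61)
  resp <- 8 / (1 + (cgrid / 35)^3)
  base <- ec50(cgrid, resp)$ec50
  for (ab in list(c(2, 0), c(0.5, 10), c(7, -3))) {
    expect_equal(ec50(cgrid, ab[1] * resp + ab[2])$ec50, base)
  }
  flat <- ec50(cgrid, rep(1, 61))
  expect_true(is.na(flat$ec50))
  expect_identical(flat$flag, "flat")
  # near-flat curves are only suppressed when a minimum effect is demanded
  wiggle <- 1 + 0.01 * sin(cgrid / 10)
  expect_identical(ec50(cgrid, wiggle, min_effect = 0.05)$flag, "flat")
  expect_identical(ec50(cgrid, wiggle)$flag, "ok")
})

test_that("ec50 takes the first crossing of a non-monotone curve", {
  cgrid <- seq(0, 100, length.out = 201)
  # dips below the midpoint early, recovers, then falls again
  resp <- 1 - 0.8 * exp(-(cgrid - 30)^2 / 50) - pmax(cgrid - 70, 0) / 30
  e <- ec50(cgrid, resp)
  first_below <- cgrid[which(resp < e$level)[1]]
  expect_lte(e$ec50, first_below)
  expect_gte(e$ec50, cgrid[which(resp < e$level)[1] - 1])
})

test_that("toxicity integral is the trapezoid area over the acid axis", {
  expect_equal(toxicity_integral(seq(0, 120, 10), rep(1, 13)), 120)
  set.seed(13)
  cg <- sort(runif(40, 0, 120))
  resp <- runif(40)
  expect_lt(abs(toxicity_integral(cg, resp) - trapezoid_oracle(cg, resp)),
            1e-12)
  expect_equal(toxicity_integral(cg, resp / 2),
               toxicity_integral(cg, resp) / 2)
})

test_that("relative viability normalizes within strain-channel groups", {
  expect_equal(relative_viability(5), 1)
  expect_equal(relative_viability(c(2, 1, 0.5)), c(1, 0.5, 0.25))
  # scale invariance
  v <- c(3, 1.2, 0.4)
  for (c0 in c(0.01, 1, 250)) {
    expect_equal(relative_viability(c0 * v), relative_viability(v))
  }
  # groups normalize independently; exactly one 1 per group
  ints <- c(4, 2, 10, 5)
  rv <- relative_viability(ints, strain = c("wt", "wt", "hap4", "hap4"))
  expect_equal(rv, c(1, 0.5, 1, 0.5))
  expect_true(all(rv >= 0 & rv <= 1))
  expect_error(relative_viability(c(-1, 2)), "nonnegative")
  expect_warning(relative_viability(c(0, 0)), "all-zero")
})

test_that("dose-response slices drive EC50 and viability through a fitted surface", {
  # deterministic synthetic surface: inhibition steeper at low pH
  g <- expand.grid(ph = seq(2.5, 7, length.out = 8),
                   acetic_acid_mM = seq(0, 120, length.out = 8))
  g$y <- 20 / (1 + (g$acetic_acid_mM / (15 + 12 * g$ph))^3)
  factors <- list(factor_spec("ph", 2.5, 7, "linear"),
                  factor_spec("acetic_acid_mM", 0, 120, "linear"))
  fit <- gp_rsm(y ~ ph + acetic_acid_mM, g, factors = factors, seed = 1)
  dr <- dose_response(fit, fixed = list(ph = 3), grid = 101)
  expect_equal(nrow(dr), 101)
  expect_equal(range(dr$acid_mM), c(0, 120))
  tt <- toxicity_table(fit, ph = c(3, 5, 6.5), glucose_g_l = 20,
                       strain = "wt")
  expect_equal(nrow(tt), 3)
  # shallower inhibition at high pH: EC50 increases with pH
  expect_true(all(diff(tt$ec50_mM) > 0))
  expect_equal(max(tt$relative_viability), 1)
  # the o2 direction reflects the curve before computing metrics
  g2 <- g; g2$y <- max(g$y) - g$y
  fit2 <- gp_rsm(y ~ ph + acetic_acid_mM, g2, factors = factors, seed = 1)
  t2 <- toxicity_table(fit2, ph = c(3, 5, 6.5), glucose_g_l = 20,
                       strain = "wt", channel = "O2_saturation",
                       direction = "o2")
  expect_true(all(grepl("o2_reflected", t2$flags)))
  expect_equal(t2$ec50_mM, tt$ec50_mM, tolerance = 0.05)
})
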