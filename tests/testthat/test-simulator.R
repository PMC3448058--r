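test_that("undissociated fraction follows Henderson-Hasselbalch", {
  expect_equal(undissociated_fraction(4.76, 4.76), 0.5)
  expect_equal(undissociated_fraction(2.76, 4.76), 1 / (1 + 1e-2))
  expect_equal(undissociated_fraction(7.76, 4.76), 1 / (1 + 1e3))
  ph <- seq(2, 8, 0.1)
  expect_true(all(diff(undissociated_fraction(ph)) < 0))
})

test_that("early growth rate approaches the Monod limit without acid", {
  p <- sim_params(noise_sd = 0)
  cond <- list(glucose_g_l = 20, ph = 5, acetic_acid_mM = 0,
               strain = "wild-type")
  g <- simulate_growth_curve(cond, p)
  k <- growth_kinetics(g$time_min, g$value, window = 3)
  mu_expected <- p$mu_max * 20 / (p$Ks + 20)
  expect_lt(abs(k$mu_values[1] - mu_expected) / mu_expected, 0.01)
})

test_that("overwhelming acid stress suppresses growth entirely", {
  p <- sim_params(noise_sd = 0)
  cond <- list(glucose_g_l = 20, ph = 2.5, acetic_acid_mM = 120,
               strain = "wild-type")
  g <- simulate_growth_curve(cond, p)
  expect_lt(max(g$value), 1.05 * p$od0)
})

test_that("the fixed-step integrator agrees with a 10x finer step", {
  p <- sim_params(noise_sd = 0, cycles = 60)
  for (cond in list(list(glucose_g_l = 20, ph = 5, acetic_acid_mM = 0,
                         strain = "wild-type"),
                    list(glucose_g_l = 5, ph = 3, acetic_acid_mM = 30,
                         strain = "hap4"))) {
    coarse <- acetox:::integrate_growth(cond, p, n_sub = 10L)
    fine <- acetox:::integrate_growth(cond, p, n_sub = 100L)
    expect_lt(max(abs(coarse$od - fine$od)), 1e-4)
  }
})

test_that("glucose is conserved up to the drain term", {
  p <- sim_params(noise_sd = 0)
  for (acid in c(0, 40, 100)) {
    tr <- acetox:::integrate_growth(
      list(glucose_g_l = 20, ph = 3, acetic_acid_mM = acid,
           strain = "wild-type"), p)
    gained <- tr$od[length(tr$od)] - p$od0
    consumed <- 20 - tr$glucose[length(tr$glucose)]
    expect_gte(p$yield_coeff * consumed + 1e-9, gained)
  }
})

test_that("final OD decreases as undissociated acid increases", {
  p <- sim_params(noise_sd = 0, cycles = 80)
  finals <- sapply(seq(0, 120, 15), function(a) {
    g <- simulate_growth_curve(list(glucose_g_l = 20, ph = 3.5,
                                    acetic_acid_mM = a,
                                    strain = "wild-type"), p)
    g$value[nrow(g)]
  })
  expect_true(all(diff(finals) <= 1e-9))
})

test_that("oxygen dynamics respect the no-consumer and steady-state limits", {
  p <- sim_params(noise_sd = 0)
  # respiration fully inhibited: saturation never drops appreciably
  o_inhib <- simulate_o2_curve(list(glucose_g_l = 20, ph = 2.5,
                                    acetic_acid_mM = 150,
                                    strain = "wild-type"), p)
  expect_gt(min(o_inhib$value), 99)
  # after glucose exhaustion OD is constant: analytic steady state
  cond <- list(glucose_g_l = 5, ph = 6.5, acetic_acid_mM = 0,
               strain = "wild-type")
  o <- simulate_o2_curve(cond, p)
  tr <- acetox:::integrate_growth(cond, p)
  od_final <- tr$od[length(tr$od)]
  sat_star <- 100 - p$our_per_od * od_final / p$kla
  sat_star <- min(max(sat_star, 0), 100)
  expect_lt(abs(o$value[nrow(o)] - sat_star) / 100, 0.001)
})

test_that("cytosolic pH holds at the setpoint and acidifies under stress", {
  p <- sim_params(noise_sd = 0, cycles = 30)
  # ample glucose, no acid, short horizon: homeostasis
  s0 <- simulate_phluorin_series(list(glucose_g_l = 40, ph = 5,
                                      acetic_acid_mM = 0,
                                      strain = "wild-type"), p)
  expect_true(all(abs(s0$ph_in - 7.2) < 1e-12))
  # strong acid stress at low pH: early acidification toward medium pH
  pfull <- sim_params(noise_sd = 0)
  s1 <- simulate_phluorin_series(list(glucose_g_l = 20, ph = 5,
                                      acetic_acid_mM = 150,
                                      strain = "wild-type"), pfull)
  expect_lt(s1$ph_in[nrow(s1)], 5.5)
  # higher glucose delays the acidification onset
  onset <- function(glu) {
    s <- simulate_phluorin_series(list(glucose_g_l = glu, ph = 3,
                                       acetic_acid_mM = 0,
                                       strain = "wild-type"), pfull)
    below <- which(s$ph_in < 7.2 - 1e-9)
    if (length(below)) s$time_min[below[1]] else Inf
  }
  expect_gt(onset(40), onset(5))
})

test_that("plate simulation is deterministic and composes per-well runs", {
  des <- space_filling_design(default_factors(), 4, seed = 2,
                              strains = c("wild-type", "hap4"))
  p <- sim_params(noise_sd = 0, cycles = 20)
  plate <- simulate_experiment(des, p, seed = 9)
  expect_equal(nrow(plate), 8 * 3 * 20)
  expect_equal(length(unique(plate$well)), 8)
  expect_identical(plate, simulate_experiment(des, p, seed = 9))
  # noiseless output equals the single-curve simulators
  w1 <- plate[plate$well == "W001" & plate$channel == "OD620", ]
  direct <- simulate_growth_curve(as.list(des[1, ]), p)
  expect_equal(w1$value, direct$value)
  # noise changes values but not structure, and is seed-stable
  pn <- sim_params(noise_sd = 0.02, cycles = 20)
  n1 <- simulate_experiment(des, pn, channels = "od", seed = 4)
  n2 <- simulate_experiment(des, pn, channels = "od", seed = 4)
  n3 <- simulate_experiment(des, pn, channels = "od", seed = 5)
  expect_identical(n1, n2)
  expect_false(identical(n1$value, n3$value))
  expect_error(simulate_growth_curve(
    list(glucose_g_l = 500, ph = 3, acetic_acid_mM = 0,
         strain = "wild-type"), p), "validity")
})
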