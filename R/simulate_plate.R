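#' Fraction of undissociated (membrane-permeant) acid
#'
#' Only the neutral, undissociated form of a weak acid crosses the plasma
#' membrane; its fraction follows the Henderson-Hasselbalch relation
#' \deqn{f_{HA} = 1 / (1 + 10^{pH - pKa}),} strictly decreasing in pH.
#' Raising the medium pH above the pKa therefore removes most of the toxic
#' species at a fixed total acid concentration.
#'
#' @param ph Extracellular pH.
#' @param pKa Acid dissociation constant (default 4.76, acetic acid at
#'   25 degrees C).
#' @return Fraction in \eqn{(0, 1)}.
#' @examples
#' undissociated_fraction(4.76) # 0.5
#' @export
undissociated_fraction <- function(ph, pKa = 4.76) {
  1 / (1 + 10^(ph - pKa))
}

#' Simulation parameters for the synthetic plate experiment
#'
#' Mechanistic parameters of the synthetic batch-culture simulator: Monod
#' growth on glucose, Hill-type growth inhibition by the undissociated
#' acetic-acid concentration, oxygen mass transfer against cellular uptake,
#' and an ATP-costly gluconeogenic/storage-carbohydrate drain that diverts
#' glucose from biomass under strong acid stress. Strain modifiers encode
#' the respiratory-deficient comparator strain (a `hap4` deletion-like
#' strain): a slightly reduced intrinsic growth rate, a higher effective
#' inhibition constant, and a near-absent gluconeogenic drain, which
#' together make it less sensitive to acetic acid at low pH. These
#' modifiers are free model parameters chosen to reproduce the qualitative
#' strain contrast, not measured quantities.
#'
#' @param mu_max Intrinsic maximal specific growth rate (1/h).
#' @param Ks Monod half-saturation constant for glucose (g/l).
#' @param yield_coeff Biomass yield (OD620 units per g/l glucose).
#' @param pKa Acetic-acid dissociation constant (pH units).
#' @param Ki Undissociated-acid concentration halving growth (mM) at
#'   reference conditions (extracellular pH equal to the pKa, no glucose
#'   protection).
#' @param hill Hill steepness of the inhibition (>= 1).
#' @param resp_Ki Undissociated-acid concentration halving respiration (mM).
#' @param ph_sensitization Log10 change of the effective inhibition
#'   constant per pH unit: `Ki_eff = Ki * 10^(ph_sensitization * (ph -
#'   pKa))`. A positive value means cells tolerate less undissociated acid
#'   at low extracellular pH, where every protonation cycle dissipates a
#'   steeper proton gradient; 0 recovers pure Henderson-Hasselbalch
#'   potency. Applied to growth and respiratory inhibition alike.
#' @param glucose_protection Strength of the glucose-fuelled
#'   (ATP-dependent) protection: the growth `Ki` is multiplied by
#'   `1 + glucose_protection * S0 / (S0 + Kg_protection)`, so the default 2
#'   allows up to a 3-fold tolerance gain at saturating glucose. Set to 0
#'   to disable.
#' @param Kg_protection Half-saturation glucose concentration of the
#'   protection effect (g/l).
#' @param kla Volumetric oxygen transfer coefficient (1/h).
#' @param our_per_od Oxygen uptake rate per OD unit (% saturation/h).
#' @param drain_rate Glucose drain under strong acid stress (g/l/h per OD).
#' @param tau_acid Time constant of cytosolic acidification (h).
#' @param ph_in0 Initial/homeostatic intracellular pH.
#' @param strain_modifiers Named list of per-strain multipliers on
#'   `mu_max`, `Ki`, `resp_Ki` and `gluconeogenic_drain`.
#' @param noise_sd Multiplicative log-normal reader noise (sdlog); 0 for
#'   noiseless simulations.
#' @param od0 Inoculum density (OD620).
#' @param cycles Number of reader cycles (default 114).
#' @param dt Reader interval in minutes (default 10).
#' @return List of class `"sim_params"`.
#' @export
sim_params <- function(mu_max = 0.45, Ks = 0.5, yield_coeff = 0.07,
                       pKa = 4.76, Ki = 40, hill = 4, resp_Ki = 30,
                       ph_sensitization = 0.2, glucose_protection = 2,
                       Kg_protection = 20,
                       kla = 2, our_per_od = 80, drain_rate = 1,
                       tau_acid = 2, ph_in0 = 7.2,
                       strain_modifiers = list(
                         `wild-type` = c(mu_max = 1, Ki = 1, resp_Ki = 1,
                                         gluconeogenic_drain = 1),
                         hap4 = c(mu_max = 0.9, Ki = 1.5, resp_Ki = 1,
                                  gluconeogenic_drain = 0.05)),
                       noise_sd = 0.02, od0 = 0.2, cycles = 114L, dt = 10) {
  p <- list(mu_max = mu_max, Ks = Ks, yield_coeff = yield_coeff, pKa = pKa,
            Ki = Ki, hill = hill, resp_Ki = resp_Ki,
            ph_sensitization = ph_sensitization,
            glucose_protection = glucose_protection,
            Kg_protection = Kg_protection, kla = kla,
            our_per_od = our_per_od, drain_rate = drain_rate,
            tau_acid = tau_acid, ph_in0 = ph_in0,
            strain_modifiers = strain_modifiers, noise_sd = noise_sd,
            od0 = od0, cycles = as.integer(cycles), dt = dt)
  with(p, stopifnot(mu_max > 0, Ks > 0, yield_coeff > 0, Ki > 0, hill >= 1,
                    resp_Ki > 0, ph_sensitization >= 0,
                    glucose_protection >= 0, Kg_protection > 0,
                    kla > 0, our_per_od > 0, drain_rate >= 0,
                    tau_acid > 0, noise_sd >= 0, od0 > 0, cycles >= 2L,
                    dt > 0))
  structure(p, class = "sim_params")
}

# pH-sensitized, optionally glucose-protected inhibition constant
effective_ki <- function(ki, condition, params, protect = FALSE) {
  ki <- ki * 10^(params$ph_sensitization * (condition$ph - params$pKa))
  if (protect && params$glucose_protection > 0) {
    s0 <- condition$glucose_g_l
    ki <- ki * (1 + params$glucose_protection *
                  s0 / (s0 + params$Kg_protection))
  }
  ki
}

# resolve strain multipliers (unknown strains behave like wild type)
strain_mods <- function(params, strain) {
  m <- params$strain_modifiers[[strain]]
  base <- c(mu_max = 1, Ki = 1, resp_Ki = 1, gluconeogenic_drain = 1)
  if (is.null(m)) return(base)
  base[names(m)] <- m
  base
}

# Core batch-culture integrator: fixed-step RK4 at dt/10 internal step on
# (OD, S). Growth is Monod in glucose with Hill inhibition by the constant
# undissociated-acid concentration HA; the gluconeogenic drain removes
# glucose without biomass gain once the inhibition exceeds 50%.
integrate_growth <- function(condition, params, n_sub = 10L) {
  mods <- strain_mods(params, condition$strain)
  mu_max <- params$mu_max * mods[["mu_max"]]
  Ki <- effective_ki(params$Ki * mods[["Ki"]], condition, params,
                     protect = TRUE)
  drain <- params$drain_rate * mods[["gluconeogenic_drain"]]
  HA <- condition$acetic_acid_mM *
    undissociated_fraction(condition$ph, params$pKa)
  inhib_term <- (HA / Ki)^params$hill
  gfac <- 1 / (1 + inhib_term)                    # growth retained
  drain_on <- inhib_term / (1 + inhib_term) > 0.5 # inhibition beyond 50%
  h <- params$dt / 60 / n_sub                     # internal step (h)
  n_steps <- (params$cycles - 1L) * n_sub
  od <- numeric(n_steps + 1L)
  s <- numeric(n_steps + 1L)
  od[1L] <- params$od0
  s[1L] <- condition$glucose_g_l
  deriv <- function(state) {
    S <- max(state[2L], 0)
    mu <- mu_max * S / (params$Ks + S) * gfac
    dOD <- mu * state[1L]
    dS <- -(mu / params$yield_coeff) * state[1L] -
      (if (drain_on && S > 0) drain * state[1L] else 0)
    c(dOD, dS)
  }
  state <- c(od[1L], s[1L])
  for (i in seq_len(n_steps)) {
    k1 <- deriv(state)
    k2 <- deriv(state + h / 2 * k1)
    k3 <- deriv(state + h / 2 * k2)
    k4 <- deriv(state + h * k3)
    state <- state + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    state[2L] <- max(state[2L], 0)
    if (any(!is.finite(state)))
      stop("non-finite state while simulating condition (glucose ",
           condition$glucose_g_l, " g/l, pH ", condition$ph, ", acid ",
           condition$acetic_acid_mM, " mM)", call. = FALSE)
    od[i + 1L] <- state[1L]
    s[i + 1L] <- state[2L]
  }
  keep <- seq(1L, n_steps + 1L, by = n_sub)
  list(time_min = (seq_len(params$cycles) - 1L) * params$dt,
       od = od[keep], glucose = s[keep],
       od_fine = od, glucose_fine = s, h = h,
       HA = HA, inhibition = inhib_term / (1 + inhib_term),
       gfac = gfac)
}

apply_noise <- function(values, noise_sd, seed) {
  if (noise_sd <= 0) return(values)
  set.seed(as.integer(seed))
  values * exp(stats::rnorm(length(values), 0, noise_sd))
}

check_condition <- function(condition) {
  stopifnot(is.list(condition) || is.data.frame(condition))
  req <- c("glucose_g_l", "ph", "acetic_acid_mM", "strain")
  if (!all(req %in% names(condition)))
    stop("condition needs fields: ", paste(req, collapse = ", "),
         call. = FALSE)
  if (condition$glucose_g_l < 0 || condition$glucose_g_l > 100)
    stop("glucose outside simulator validity (0-100 g/l)", call. = FALSE)
  if (condition$acetic_acid_mM < 0 || condition$acetic_acid_mM > 200)
    stop("acetic acid outside simulator validity (0-200 mM)", call. = FALSE)
  if (condition$ph <= 0 || condition$ph >= 14)
    stop("pH outside (0, 14)", call. = FALSE)
  invisible(condition)
}

#' Simulate an OD620 growth curve
#'
#' Integrates the batch-culture model `dOD/dt = mu OD`,
#' `dS/dt = -(mu / Y) OD - drain`, with
#' `mu = mu_max S/(Ks + S) / (1 + (HA/Ki_eff)^hill)`, `HA` the
#' undissociated acetic-acid concentration of the condition and `Ki_eff`
#' the pH-sensitized, glucose-protected inhibition constant (see
#' [sim_params()]), by fixed-step fourth-order Runge-Kutta at one tenth of
#' the reader interval. Readings are emitted at the reader cadence with
#' multiplicative log-normal noise.
#'
#' @param condition List/row with `glucose_g_l`, `ph`, `acetic_acid_mM`,
#'   `strain`.
#' @param params A [sim_params()].
#' @param seed Integer seed for the reader noise.
#' @return `data.frame` with `time_min` and `value` (OD620), condition in
#'   the `"condition"` attribute.
#' @export
simulate_growth_curve <- function(condition, params = sim_params(),
                                  seed = 1L) {
  check_condition(condition)
  tr <- integrate_growth(condition, params)
  out <- data.frame(time_min = tr$time_min,
                    value = apply_noise(tr$od, params$noise_sd, seed))
  attr(out, "condition") <- condition
  attr(out, "channel") <- "OD620"
  out
}

#' Simulate an oxygen-saturation curve
#'
#' Couples dissolved-oxygen dynamics to the growth trajectory:
#' `d(sat)/dt = kla (100 - sat) - OUR_per_OD * OD(t) * R(HA)`, where the
#' respiratory activity `R(HA) = 1 / (1 + (HA/resp_Ki)^hill)` is inhibited
#' by undissociated acid. Saturation is clamped to \eqn{[0, 100]}%. When
#' respiration is fully inhibited the curve stays near the sterile 100%
#' line, so a high oxygen integral indicates low oxygen consumption.
#'
#' @inheritParams simulate_growth_curve
#' @return `data.frame` with `time_min` and `value` (% air saturation).
#' @export
simulate_o2_curve <- function(condition, params = sim_params(), seed = 1L) {
  check_condition(condition)
  mods <- strain_mods(params, condition$strain)
  tr <- integrate_growth(condition, params)
  resp_Ki <- effective_ki(params$resp_Ki * mods[["resp_Ki"]], condition,
                          params, protect = FALSE)
  R <- 1 / (1 + (tr$HA / resp_Ki)^params$hill)
  n_fine <- length(tr$od_fine)
  sat <- numeric(n_fine)
  sat[1L] <- 100
  h <- tr$h
  dsat <- function(s, od) params$kla * (100 - s) - params$our_per_od * od * R
  for (i in seq_len(n_fine - 1L)) {
    od_mid <- (tr$od_fine[i] + tr$od_fine[i + 1L]) / 2
    k1 <- dsat(sat[i], tr$od_fine[i])
    k2 <- dsat(sat[i] + h / 2 * k1, od_mid)
    k3 <- dsat(sat[i] + h / 2 * k2, od_mid)
    k4 <- dsat(sat[i] + h * k3, tr$od_fine[i + 1L])
    sat[i + 1L] <- sat[i] + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    sat[i + 1L] <- min(max(sat[i + 1L], 0), 100)
  }
  keep <- seq(1L, n_fine, by = round((n_fine - 1L) / (params$cycles - 1L)))
  vals <- apply_noise(sat[keep], params$noise_sd, seed)
  out <- data.frame(time_min = tr$time_min,
                    value = pmin(pmax(vals, 0), 110))
  attr(out, "condition") <- condition
  attr(out, "channel") <- "O2_saturation"
  out
}

#' Simulate a pHluorin fluorescence-ratio series
#'
#' Cytosolic pH starts at the homeostatic setpoint (7.2) and is maintained
#' there while glucose remains and acid inhibition stays below 50% (ATP is
#' available to export protons). Once either fails, the cytosolic pH decays
#' exponentially toward the extracellular pH with time constant `tau_acid`,
#' so acid stress at low pH produces much earlier cytosolic acidification
#' and higher glucose delays the onset. The intracellular pH trajectory is
#' pushed through the forward calibration map to give the observable
#' 390/480 ratio; pH outside the calibrated range is clamped to the nearest
#' knot (flagged in the returned truth).
#'
#' @inheritParams simulate_growth_curve
#' @param cal A [ph_calibration()] used as the sensor's forward model.
#' @return `data.frame` with `time_min`, `value` (ratio), plus the ground
#'   truth `ph_in` and logical `clamped` columns for validation.
#' @export
simulate_phluorin_series <- function(condition, params = sim_params(),
                                     cal = default_ph_calibration(),
                                     seed = 1L) {
  check_condition(condition)
  stopifnot(inherits(cal, "ph_calibration"))
  tr <- integrate_growth(condition, params)
  t_h <- tr$time_min / 60
  glucose_gone <- tr$glucose <= 1e-3
  onset_idx <- if (tr$inhibition >= 0.5) 1L else
    if (any(glucose_gone)) which(glucose_gone)[1L] else NA_integer_
  ph_in <- rep(params$ph_in0, length(t_h))
  if (!is.na(onset_idx)) {
    t0 <- t_h[onset_idx]
    idx <- t_h >= t0
    ph_in[idx] <- condition$ph +
      (params$ph_in0 - condition$ph) * exp(-(t_h[idx] - t0) / params$tau_acid)
  }
  lo <- min(cal$ph_knots); hi <- max(cal$ph_knots)
  clamped <- ph_in < lo | ph_in > hi
  ratio <- ph_to_ratio(cal, pmin(pmax(ph_in, lo), hi))
  out <- data.frame(time_min = tr$time_min,
                    value = apply_noise(ratio, params$noise_sd, seed),
                    ph_in = ph_in, clamped = clamped)
  attr(out, "condition") <- condition
  attr(out, "channel") <- "ratio_390_480"
  out
}

#' Simulate a full multifactorial plate experiment
#'
#' Runs the per-well simulators over every condition of a design and
#' assembles the long-format plate table the analysis pipeline consumes.
#' Per-well child seeds are derived deterministically from the master seed,
#' so the whole dataset is reproducible bit-for-bit.
#'
#' @param design `data.frame` with columns `glucose_g_l`, `ph`,
#'   `acetic_acid_mM` and optionally `strain` (default `"wild-type"`).
#' @param params A [sim_params()].
#' @param channels Subset of `c("od", "o2", "ph")`.
#' @param cal pHluorin calibration for the `"ph"` channel.
#' @param seed Master integer seed.
#' @return Long-format plate `data.frame` with columns `well, strain,
#'   glucose_g_l, ph, acetic_acid_mM, channel, time_min, value`.
#' @examples
#' d <- space_filling_design(default_factors(), 4, seed = 1,
#'                           strains = "wild-type")
#' plate <- simulate_experiment(d, sim_params(noise_sd = 0), channels = "od")
#' @export
simulate_experiment <- function(design, params = sim_params(),
                                channels = c("od", "o2", "ph"),
                                cal = default_ph_calibration(), seed = 1L) {
  stopifnot(is.data.frame(design), nrow(design) >= 1L)
  channels <- match.arg(channels, several.ok = TRUE)
  if (is.null(design$strain)) design$strain <- "wild-type"
  chan_name <- c(od = "OD620", o2 = "O2_saturation", ph = "ratio_390_480")
  rows <- vector("list", nrow(design) * length(channels))
  k <- 0L
  for (i in seq_len(nrow(design))) {
    cond <- as.list(design[i, c("glucose_g_l", "ph", "acetic_acid_mM",
                                "strain")])
    well <- sprintf("W%03d", i)
    for (ch in channels) {
      k <- k + 1L
      child <- (as.integer(seed) + 7919L * i +
                  104729L * match(ch, c("od", "o2", "ph"))) %% 2147483647L
      ser <- switch(ch,
        od = simulate_growth_curve(cond, params, seed = child),
        o2 = simulate_o2_curve(cond, params, seed = child),
        ph = simulate_phluorin_series(cond, params, cal = cal, seed = child))
      rows[[k]] <- data.frame(
        well = well, strain = cond$strain, glucose_g_l = cond$glucose_g_l,
        ph = cond$ph, acetic_acid_mM = cond$acetic_acid_mM,
        channel = chan_name[[ch]], time_min = ser$time_min,
        value = ser$value, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
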