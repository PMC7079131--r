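# Synthetic whole-cell voltage-clamp families with known ground truth.
#
# The simulator shares its forward model with the fitting stage
# (ephys-model.R).  Each generator returns a `trace_set` whose `truth`
# attribute records every parameter used, so downstream fits can be scored
# as parameter-recovery experiments.

# Default bell-shaped time-constant curves (ms as a function of mV).  The
# activation time constant peaks near the activation midpoint in the
# 0.15-0.5 ms range; the inactivation time constant peaks near the
# inactivation midpoint and spans roughly 0.5-5 ms, the scale typical of
# fast cardiac sodium current kinetics.
default_tau_m <- function(act_vhalf = -42.62) {
  force(act_vhalf)
  function(v) 0.15 + 0.35 * exp(-((v - act_vhalf) / 30)^2)
}

default_tau_h <- function(inact_vhalf = -96.14) {
  force(inact_vhalf)
  function(v) 0.5 + 4.5 * exp(-((v - inact_vhalf) / 35)^2)
}

#' Configuration for synthetic voltage-clamp families
#'
#' Bundles the ground-truth channel parameters used by
#' [simulate_activation_family()], [simulate_inactivation_family()] and
#' [simulate_recovery_family()].  Defaults correspond to a cardiac sodium
#' channel expressed without auxiliary subunits: activation midpoint
#' -42.62 mV (slope 7.28 mV), inactivation midpoint -96.14 mV (slope
#' 7.17 mV), reversal 19.58 mV.
#'
#' @param gmax maximal conductance (nS), positive.
#' @param e_na reversal potential (mV).
#' @param act_vhalf,act_k activation Boltzmann midpoint and slope (mV);
#'   `act_k > 0`.
#' @param inact_vhalf,inact_k inactivation Boltzmann midpoint and slope
#'   (mV); `inact_k > 0`.
#' @param tau_m_of_v,tau_h_of_v functions mapping voltage (mV) to the
#'   activation / inactivation time constants (ms); must be strictly
#'   positive over the clamp range.
#' @param offset constant leak conductance (nS).
#' @param c_m cell capacitance (pF), positive.
#' @param noise_sd additive Gaussian current noise (pA), non-negative.
#' @param dt_ms sampling interval (ms); default 0.008 ms (125 kHz).
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @return An object of class `ephys_sim_config`.
#' @export
ephys_sim_config <- function(gmax = 75, e_na = 19.58,
                             act_vhalf = -42.62, act_k = 7.28,
                             inact_vhalf = -96.14, inact_k = 7.17,
                             tau_m_of_v = default_tau_m(act_vhalf),
                             tau_h_of_v = default_tau_h(inact_vhalf),
                             offset = 0, c_m = 12, noise_sd = 20,
                             dt_ms = 0.008, seed = NULL) {
  check_scalar(gmax, "gmax", lower = 0, strict_lower = TRUE)
  check_scalar(e_na, "e_na")
  check_scalar(act_vhalf, "act_vhalf")
  check_scalar(act_k, "act_k", lower = 0, strict_lower = TRUE)
  check_scalar(inact_vhalf, "inact_vhalf")
  check_scalar(inact_k, "inact_k", lower = 0, strict_lower = TRUE)
  check_scalar(offset, "offset")
  check_scalar(c_m, "c_m", lower = 0, strict_lower = TRUE)
  check_scalar(noise_sd, "noise_sd", lower = 0)
  check_scalar(dt_ms, "dt_ms", lower = 0, strict_lower = TRUE)
  check_that(is.function(tau_m_of_v), "tau_m_of_v", "must be a function")
  check_that(is.function(tau_h_of_v), "tau_h_of_v", "must be a function")
  probe <- seq(-140, 40, by = 10)
  check_that(all(tau_m_of_v(probe) > 0), "tau_m_of_v",
             "must be strictly positive over the clamp range")
  check_that(all(tau_h_of_v(probe) > 0), "tau_h_of_v",
             "must be strictly positive over the clamp range")
  structure(list(gmax = gmax, e_na = e_na,
                 act_vhalf = act_vhalf, act_k = act_k,
                 inact_vhalf = inact_vhalf, inact_k = inact_k,
                 tau_m_of_v = tau_m_of_v, tau_h_of_v = tau_h_of_v,
                 offset = offset, c_m = c_m, noise_sd = noise_sd,
                 dt_ms = dt_ms, seed = seed),
            class = "ephys_sim_config")
}

act_params <- function(cfg) boltzmann_params(cfg$act_vhalf, cfg$act_k, "activation")
inact_params <- function(cfg) boltzmann_params(cfg$inact_vhalf, cfg$inact_k, "inactivation")

#' Maximal conductance matching a target peak current density
#'
#' Solves for the `gmax` that makes the noise-free activation family reach
#' a given peak current density (pA/pF).  Peak current scales linearly with
#' `gmax`, so the solution is exact.
#'
#' @param density_pa_pf target peak current density (pA/pF), positive.
#' @param cfg an [ephys_sim_config()] whose remaining parameters define the
#'   family.
#' @param v_test test voltages of the activation protocol.
#' @param v_hold holding voltage (mV); the resting availability
#'   `h(v_hold)` attenuates the peak and is accounted for.
#' @return `gmax` in nS.
#' @export
gmax_for_peak_density <- function(density_pa_pf, cfg,
                                  v_test = seq(-90, 35, by = 5),
                                  v_hold = -120) {
  check_scalar(density_pa_pf, "density_pa_pf", lower = 0, strict_lower = TRUE)
  act <- act_params(cfg)
  h0 <- boltzmann_curve(v_hold, inact_params(cfg))
  per_unit <- max(abs(boltzmann_curve(v_test, act) * (v_test - cfg$e_na))) * h0
  density_pa_pf * cfg$c_m / per_unit
}

# Construct a trace_set from a long sweep table.
trace_set <- function(sweeps, c_m, protocol, truth = NULL) {
  structure(list(sweeps = sweeps, c_m = c_m, protocol = protocol,
                 truth = truth),
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("trace_set: %s protocol, %d sweeps, c_m = %.1f pF\n",
              x$protocol$kind, length(unique(x$sweeps$sweep)), x$c_m))
  invisible(x)
}

# Unit-peak m3h conductance shape at one voltage (gmax = 1, offset = 0),
# together with its analytic peak value.  Used by the steady-state
# amplitude convention (see simulate_activation_family).
m3h_shape <- function(t, m0, m_inf, h0, h_inf, tau_m, tau_h) {
  m <- m_inf - (m_inf - m0) * exp(-t / tau_m)
  h <- h_inf - (h_inf - h0) * exp(-t / tau_h)
  m^3 * h
}

#' Simulate a steady-state activation family
#'
#' Generates one 50-ms test sweep per voltage from a -120 mV holding
#' potential (default -90 to +35 mV in 5 mV steps, 26 sweeps).  Two
#' amplitude conventions are available:
#'
#' * `"steady_state"` (default): each sweep's peak conductance equals
#'   `gmax * act(V) * h0` exactly, with the m3h time-course shape scaled to
#'   that peak.  The steady-state analysis (peak currents, reversal,
#'   Boltzmann fit) then inverts the generator exactly in the noise-free
#'   limit.
#' * `"hh"`: the raw m3h forward model; peak conductance carries the
#'   physical attenuation from inactivation during the rising phase.  Use
#'   this convention to exercise the kinetic (time-constant) fits.
#'
#' @param cfg an [ephys_sim_config()].
#' @param v_test test voltages (mV).
#' @param v_hold holding voltage (mV).
#' @param pulse_ms test-pulse duration (ms).
#' @param amplitude amplitude convention, see Details.
#' @return A `trace_set` with protocol `"activation"`; its `truth` field
#'   records the configuration, per-sweep true peak currents and
#'   conductances.
#' @export
simulate_activation_family <- function(cfg, v_test = seq(-90, 35, by = 5),
                                       v_hold = -120, pulse_ms = 50,
                                       amplitude = c("steady_state", "hh")) {
  stopifnot(inherits(cfg, "ephys_sim_config"))
  amplitude <- match.arg(amplitude)
  act <- act_params(cfg)
  inact <- inact_params(cfg)
  t <- seq(0, pulse_ms, by = cfg$dt_ms)
  m0 <- boltzmann_curve(v_hold, act)^(1 / 3)
  h0 <- boltzmann_curve(v_hold, inact)

  with_seed(cfg$seed, {
    per_sweep <- lapply(seq_along(v_test), function(i) {
      v <- v_test[i]
      m_inf <- boltzmann_curve(v, act)^(1 / 3)
      h_inf <- boltzmann_curve(v, inact)
      tau_m <- cfg$tau_m_of_v(v)
      tau_h <- cfg$tau_h_of_v(v)
      shape <- m3h_shape(t, m0, m_inf, h0, h_inf, tau_m, tau_h)
      if (amplitude == "steady_state") {
        peak_g <- cfg$gmax * boltzmann_curve(v, act) * h0
        pk <- max(shape)
        g <- if (pk > 0) peak_g * shape / pk else rep(0, length(t))
      } else {
        g <- cfg$gmax * shape
        peak_g <- cfg$gmax * max(shape)
      }
      g <- g + cfg$offset
      i_pa <- g * (v - cfg$e_na)
      if (cfg$noise_sd > 0)
        i_pa <- i_pa + rnorm(length(t), sd = cfg$noise_sd)
      list(df = data.frame(sweep = i, v_mV = v, time_ms = t, i_pA = i_pa),
           peak_g = peak_g + cfg$offset,
           peak_i = (peak_g + cfg$offset) * (v - cfg$e_na),
           tau_m = tau_m, tau_h = tau_h,
           m0 = m0, m_inf = m_inf, h0 = h0, h_inf = h_inf)
    })
    sweeps <- do.call(rbind, lapply(per_sweep, `[[`, "df"))
    truth <- list(cfg = cfg, v_test = v_test, v_hold = v_hold,
                  amplitude = amplitude,
                  peak_g = vapply(per_sweep, `[[`, numeric(1), "peak_g"),
                  peak_i = vapply(per_sweep, `[[`, numeric(1), "peak_i"),
                  tau_m = vapply(per_sweep, `[[`, numeric(1), "tau_m"),
                  tau_h = vapply(per_sweep, `[[`, numeric(1), "tau_h"),
                  m0 = m0, h0 = h0,
                  m_inf = vapply(per_sweep, `[[`, numeric(1), "m_inf"),
                  h_inf = vapply(per_sweep, `[[`, numeric(1), "h_inf"))
    trace_set(sweeps, cfg$c_m,
              protocol = list(kind = "activation", v_hold = v_hold,
                              v_test = v_test, pulse_ms = pulse_ms,
                              dt_ms = cfg$dt_ms),
              truth = truth)
  })
}

#' Simulate a steady-state inactivation family
#'
#' One sweep per conditioning voltage (default -140 to -50 mV in 5 mV
#' steps, 19 sweeps): a 100-ms conditioning pre-pulse (assumed long enough
#' for `h` to reach steady state) followed by a 50-ms test pulse to
#' `v_test`.  Only the test-pulse segment is rendered; the test-pulse peak
#' current scales exactly with the availability `h_inf(v_pre)`.
#'
#' @param cfg an [ephys_sim_config()].
#' @param v_pre conditioning pre-pulse voltages (mV).
#' @param v_test test-pulse voltage (mV).
#' @param pulse_ms test-pulse duration (ms).
#' @return A `trace_set` with protocol `"inactivation"`.
#' @export
simulate_inactivation_family <- function(cfg, v_pre = seq(-140, -50, by = 5),
                                         v_test = -40, pulse_ms = 50) {
  stopifnot(inherits(cfg, "ephys_sim_config"))
  act <- act_params(cfg)
  inact <- inact_params(cfg)
  t <- seq(0, pulse_ms, by = cfg$dt_ms)
  m_inf <- boltzmann_curve(v_test, act)^(1 / 3)
  h_inf <- boltzmann_curve(v_test, inact)
  tau_m <- cfg$tau_m_of_v(v_test)
  tau_h <- cfg$tau_h_of_v(v_test)

  with_seed(cfg$seed, {
    per_sweep <- lapply(seq_along(v_pre), function(i) {
      vp <- v_pre[i]
      h0 <- boltzmann_curve(vp, inact)   # availability after the pre-pulse
      m0 <- boltzmann_curve(vp, act)^(1 / 3)
      shape <- m3h_shape(t, m0, m_inf, h0, h_inf, tau_m, tau_h)
      peak_g <- cfg$gmax * boltzmann_curve(v_test, act) * h0
      pk <- max(shape)
      g <- if (pk > 0) peak_g * shape / pk else rep(0, length(t))
      g <- g + cfg$offset
      i_pa <- g * (v_test - cfg$e_na)
      if (cfg$noise_sd > 0)
        i_pa <- i_pa + rnorm(length(t), sd = cfg$noise_sd)
      list(df = data.frame(sweep = i, v_mV = vp, time_ms = t, i_pA = i_pa),
           peak_i = (peak_g + cfg$offset) * (v_test - cfg$e_na),
           availability = h0)
    })
    sweeps <- do.call(rbind, lapply(per_sweep, `[[`, "df"))
    truth <- list(cfg = cfg, v_pre = v_pre, v_test = v_test,
                  peak_i = vapply(per_sweep, `[[`, numeric(1), "peak_i"),
                  availability = vapply(per_sweep, `[[`, numeric(1),
                                        "availability"))
    trace_set(sweeps, cfg$c_m,
              protocol = list(kind = "inactivation", v_hold = -120,
                              v_pre = v_pre, v_test = v_test,
                              pulse_ms = pulse_ms, dt_ms = cfg$dt_ms),
              truth = truth)
  })
}

#' Simulate a two-pulse recovery-from-inactivation family
#'
#' Each sweep delivers two identical 50-ms depolarizing pulses to
#' `v_pulse` (P1, P2) separated by a recovery interval at the holding
#' voltage; intervals default to 3-72 ms in 3 ms steps (24 sweeps).  The
#' P2/P1 peak ratio follows `1 - exp(-interval/tau_rec)` exactly in the
#' noise-free limit.
#'
#' @param cfg an [ephys_sim_config()].
#' @param tau_rec ground-truth recovery time constant (ms), positive.
#' @param intervals recovery intervals (ms), positive.
#' @param v_pulse pulse voltage (mV).
#' @param pulse_ms pulse duration (ms).
#' @return A `trace_set` with protocol `"recovery"`; the protocol records
#'   per-sweep P1/P2 windows for [extract_recovery_ratios()].
#' @export
simulate_recovery_family <- function(cfg, tau_rec = 7.64,
                                     intervals = seq(3, 72, by = 3),
                                     v_pulse = -40, pulse_ms = 50) {
  stopifnot(inherits(cfg, "ephys_sim_config"))
  if (!is.numeric(tau_rec) || length(tau_rec) != 1L || tau_rec <= 0)
    stop("tau_rec must be > 0", call. = FALSE)
  if (any(intervals <= 0)) stop("intervals must be positive", call. = FALSE)
  act <- act_params(cfg)
  inact <- inact_params(cfg)
  v_hold <- -120
  m0 <- boltzmann_curve(v_hold, act)^(1 / 3)
  h0 <- boltzmann_curve(v_hold, inact)
  m_inf <- boltzmann_curve(v_pulse, act)^(1 / 3)
  h_inf <- boltzmann_curve(v_pulse, inact)
  tau_m <- cfg$tau_m_of_v(v_pulse)
  tau_h <- cfg$tau_h_of_v(v_pulse)
  tp <- seq(0, pulse_ms, by = cfg$dt_ms)
  shape <- m3h_shape(tp, m0, m_inf, h0, h_inf, tau_m, tau_h)
  shape <- shape / max(shape)
  peak_i <- (cfg$gmax * boltzmann_curve(v_pulse, act) * h0 + cfg$offset) *
    (v_pulse - cfg$e_na)

  with_seed(cfg$seed, {
    windows <- vector("list", length(intervals))
    per_sweep <- lapply(seq_along(intervals), function(i) {
      gap <- intervals[i]
      n_gap <- max(1L, round(gap / cfg$dt_ms))
      t_gap <- seq(cfg$dt_ms, by = cfg$dt_ms, length.out = n_gap)
      frac <- recovery_fraction(gap, tau_rec)
      t_all <- c(tp,
                 pulse_ms + t_gap,
                 pulse_ms + gap + cfg$dt_ms + tp)
      v_all <- c(rep(v_pulse, length(tp)), rep(v_hold, n_gap),
                 rep(v_pulse, length(tp)))
      i_all <- c(peak_i * shape, rep(0, n_gap), peak_i * frac * shape)
      if (cfg$noise_sd > 0)
        i_all <- i_all + rnorm(length(i_all), sd = cfg$noise_sd)
      windows[[i]] <<- list(interval = gap,
                            p1 = c(0, pulse_ms),
                            p2 = c(pulse_ms + gap + cfg$dt_ms,
                                   pulse_ms + gap + cfg$dt_ms + pulse_ms))
      data.frame(sweep = i, v_mV = v_all, time_ms = t_all, i_pA = i_all)
    })
    sweeps <- do.call(rbind, per_sweep)
    truth <- list(cfg = cfg, tau_rec = tau_rec, intervals = intervals,
                  ratio = recovery_fraction(intervals, tau_rec),
                  peak_i_p1 = peak_i)
    trace_set(sweeps, cfg$c_m,
              protocol = list(kind = "recovery", v_hold = v_hold,
                              v_pulse = v_pulse, pulse_ms = pulse_ms,
                              intervals = intervals, windows = windows,
                              dt_ms = cfg$dt_ms),
              truth = truth)
  })
}
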