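# Closed-form gating models shared by the simulator and the fitting stage.
#
# Conventions: voltages in mV, times in ms, currents in pA, conductances in
# nS (so that I[pA] = G[nS] * (V - E_Na)[mV]).  Boltzmann slope factors are
# stored positive together with an explicit activation/inactivation sense,
# which removes the sign ambiguity that otherwise creeps into inactivation
# fits.

#' Boltzmann steady-state gating parameters
#'
#' @param vhalf voltage of half-maximal activation or inactivation (mV).
#' @param k slope factor (mV), stored positive; steepness of the curve.
#'   Related to the effective gating charge via `k = RT/zF`
#'   (see [charge_from_slope()]).
#' @param sense `"activation"` (curve increases with voltage) or
#'   `"inactivation"` (curve decreases with voltage).
#' @return An object of class `boltzmann_params`.
#' @seealso [boltzmann_curve()]
#' @export
boltzmann_params <- function(vhalf, k, sense = c("activation", "inactivation")) {
  sense <- match.arg(sense)
  check_scalar(vhalf, "vhalf")
  check_scalar(k, "k", lower = 0, strict_lower = TRUE)
  structure(list(vhalf = vhalf, k = k, sense = sense),
            class = "boltzmann_params")
}

#' @export
print.boltzmann_params <- function(x, ...) {
  cat(sprintf("Boltzmann %s curve: vhalf = %.2f mV, k = %.2f mV\n",
              x$sense, x$vhalf, x$k))
  invisible(x)
}

#' Evaluate a Boltzmann steady-state gating curve
#'
#' Computes `1 / (1 + exp((V - vhalf)/k))` for inactivation and its
#' mirror-image `1 / (1 + exp((vhalf - V)/k))` for activation, so that the
#' value at `vhalf` is exactly 0.5 and activation increases with voltage.
#'
#' @param v voltage(s) in mV.
#' @param p a [boltzmann_params()] object.
#' @return Open-unit-interval fraction(s), same length as `v`.
#' @export
#' @examples
#' p <- boltzmann_params(-42.62, 7.28, "activation")
#' boltzmann_curve(-42.62, p)  # exactly 0.5
boltzmann_curve <- function(v, p) {
  stopifnot(inherits(p, "boltzmann_params"))
  s <- if (p$sense == "activation") -1 else 1
  1 / (1 + exp(s * (v - p$vhalf) / p$k))
}

#' Nernst equilibrium potential from a per-decade slope
#'
#' `slope * log10(c_out / c_in)`.  The slope is exposed as a parameter
#' (mV per tenfold concentration ratio) rather than computed from RT/F at
#' an assumed temperature; the conventional room-temperature value is
#' 58 mV/decade.
#'
#' @param c_out,c_in extracellular and intracellular concentrations (mM).
#' @param slope_mv_per_decade slope in mV per decade (default 58).
#' @return Equilibrium potential in mV.
#' @export
#' @examples
#' nernst_potential(70, 35)  # ~17.46 mV for a physiological Na+ gradient
nernst_potential <- function(c_out, c_in, slope_mv_per_decade = 58) {
  if (!all(c_out > 0) || !all(c_in > 0))
    stop("concentrations must be positive", call. = FALSE)
  slope_mv_per_decade * log10(c_out / c_in)
}

#' Chord conductance from current and driving force
#'
#' `G = I / (V - E_Na)`, the ohmic conversion used to build activation
#' curves from peak currents.
#'
#' @param i current (pA).
#' @param v membrane voltage (mV).
#' @param e_na reversal potential (mV).
#' @return Conductance in nS.
#' @export
conductance_from_current <- function(i, v, e_na) {
  if (any(v == e_na))
    stop("undefined driving force: v equals e_na", call. = FALSE)
  i / (v - e_na)
}

#' Hodgkin-Huxley gating state for an m3h conductance time course
#'
#' Holds the initial and steady-state values of the activation (`m`) and
#' inactivation (`h`) variables together with their relaxation time
#' constants, the maximal conductance and a constant leak offset.
#'
#' @param m0,m_inf,h0,h_inf dimensionless gating endpoints in `[0, 1]`.
#' @param tau_m,tau_h relaxation time constants (ms), positive.
#' @param gmax maximal conductance (nS).
#' @param offset constant conductance offset (nS) absorbing the finite
#'   background membrane conductance.
#' @return An object of class `hh_state`.
#' @export
hh_state <- function(m0, m_inf, h0, h_inf, tau_m, tau_h, gmax, offset = 0) {
  for (nm in c("m0", "m_inf", "h0", "h_inf"))
    check_scalar(get(nm), nm, lower = 0, upper = 1)
  check_scalar(tau_m, "tau_m", lower = 0, strict_lower = TRUE)
  check_scalar(tau_h, "tau_h", lower = 0, strict_lower = TRUE)
  check_scalar(gmax, "gmax", lower = 0)
  check_scalar(offset, "offset")
  structure(list(m0 = m0, m_inf = m_inf, h0 = h0, h_inf = h_inf,
                 tau_m = tau_m, tau_h = tau_h, gmax = gmax, offset = offset),
            class = "hh_state")
}

#' Hodgkin-Huxley m3h conductance time course
#'
#' Evaluates
#' `G(t) = gmax * (m_inf - (m_inf - m0) exp(-t/tau_m))^3 *`
#' `(h_inf - (h_inf - h0) exp(-t/tau_h)) + offset`,
#' the analytic solution for the m3h conductance following a voltage step
#' at `t = 0`.
#'
#' @param t time(s) since the step (ms), non-negative.
#' @param s an [hh_state()] object.
#' @return Conductance in nS, same length as `t`.
#' @export
hh_m3h_timecourse <- function(t, s) {
  stopifnot(inherits(s, "hh_state"))
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  m <- s$m_inf - (s$m_inf - s$m0) * exp(-t / s$tau_m)
  h <- s$h_inf - (s$h_inf - s$h0) * exp(-t / s$tau_h)
  s$gmax * m^3 * h + s$offset
}

#' Mono-exponential recovery from inactivation
#'
#' Fractional availability `1 - exp(-t/tau)` after a recovery interval
#' `t` at the holding voltage.
#'
#' @param t recovery interval(s) (ms).
#' @param tau recovery time constant (ms), positive.
#' @return Recovered fraction(s) in `[0, 1)` for finite `t`.
#' @export
recovery_fraction <- function(t, tau) {
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0)
    stop("tau must be a positive number", call. = FALSE)
  1 - exp(-t / tau)
}

#' Double-exponential current decay parameters
#'
#' @param a1,a2 amplitudes of the fast and slow components (pA, positive
#'   for inward currents).
#' @param tau1,tau2 fast and slow time constants (ms), with
#'   `tau1 < tau2` by convention (relabelled if given the other way).
#' @return An object of class `decay_params`.
#' @export
decay_params <- function(a1, a2, tau1, tau2) {
  check_scalar(tau1, "tau1", lower = 0, strict_lower = TRUE)
  check_scalar(tau2, "tau2", lower = 0, strict_lower = TRUE)
  check_scalar(a1, "a1")
  check_scalar(a2, "a2")
  if (tau1 > tau2) {
    tmp <- tau1; tau1 <- tau2; tau2 <- tmp
    tmp <- a1; a1 <- a2; a2 <- tmp
  }
  structure(list(a1 = a1, a2 = a2, tau1 = tau1, tau2 = tau2),
            class = "decay_params")
}

#' Double-exponential inward current decay
#'
#' `y(t) = -a1 exp(-t/tau1) - a2 exp(-t/tau2)`; the two components describe
#' the fast and slow phases of sodium current inactivation.
#'
#' @param t time(s) since the peak (ms).
#' @param p a [decay_params()] object.
#' @return Current in pA (negative for inward).
#' @export
double_exp_decay <- function(t, p) {
  stopifnot(inherits(p, "decay_params"))
  -p$a1 * exp(-t / p$tau1) - p$a2 * exp(-t / p$tau2)
}

#' Effective gating charge from a Boltzmann slope factor
#'
#' Inverts `k = RT/zF`: `z = (RT/F) / k` with RT/F expressed in mV.
#'
#' @param k slope factor (mV), positive.
#' @param temperature absolute temperature (K); default 295.15 K (22 C).
#' @return Effective charge `z` in elementary charges.
#' @export
#' @examples
#' charge_from_slope(7.28)  # ~3.5 elementary charges
charge_from_slope <- function(k, temperature = 295.15) {
  if (any(k <= 0)) stop("k must be positive", call. = FALSE)
  check_scalar(temperature, "temperature", lower = 0, strict_lower = TRUE)
  gas_r <- 8.314462618   # J / (mol K)
  faraday <- 96485.33212 # C / mol
  rt_over_f_mv <- 1000 * gas_r * temperature / faraday
  rt_over_f_mv / k
}
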