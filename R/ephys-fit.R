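# Whole-cell voltage-clamp analysis: peak currents -> I/V -> reversal ->
# Boltzmann gating fits -> gating endpoints -> m3h time-constant fits ->
# decay and recovery fits -> derived quantities.
#
# Nonlinear fits use stats::nls with the "port" (trust-region, bounded)
# algorithm.  Sign convention: inward sodium current is negative; the peak
# of a sweep is the sample of largest magnitude inside the search window.

sweep_list <- function(ts) split(ts$sweeps, ts$sweeps$sweep)

#' Extract peak currents from a clamp family
#'
#' Per sweep, returns the extremum of largest magnitude inside the search
#' window, together with the capacitance-normalized current density.  The
#' first `settle_ms` after the step are excluded to skip any residual
#' capacitive transient.
#'
#' @param ts a `trace_set`.
#' @param window numeric length-2 time window (ms) searched for the peak;
#'   default the full sweep.
#' @param settle_ms initial interval excluded from the search (ms).
#' @param smooth_ms running-mean window applied before the peak search
#'   (ms); the default of 0.12 ms approximates the bandwidth of a 5 kHz
#'   acquisition filter and keeps broadband sample noise from biasing the
#'   peak upward.  Use 0 to take raw sample extrema.
#' @return A data frame with columns `v_mV`, `peak_pA`, `density_pA_pF`.
#' @export
extract_peak_currents <- function(ts, window = NULL, settle_ms = 0.3,
                                  smooth_ms = 0.12) {
  stopifnot(inherits(ts, "trace_set"))
  out <- lapply(sweep_list(ts), function(sw) {
    lo <- if (is.null(window)) -Inf else window[1]
    hi <- if (is.null(window)) Inf else window[2]
    lo <- max(lo, min(sw$time_ms) + settle_ms)
    keep <- sw$time_ms >= lo & sw$time_ms <= hi
    if (!any(keep)) stop("empty peak-search window", call. = FALSE)
    i <- sw$i_pA[keep]
    if (smooth_ms > 0 && length(sw$time_ms) > 2) {
      dt <- sw$time_ms[2] - sw$time_ms[1]
      n_avg <- max(1L, round(smooth_ms / dt))
      if (n_avg > 1 && length(i) > n_avg) {
        sm <- stats::filter(i, rep(1 / n_avg, n_avg), sides = 2)
        i <- as.numeric(sm[!is.na(sm)])
      }
    }
    pk <- i[which.max(abs(i))]
    data.frame(v_mV = sw$v_mV[1], peak_pA = pk,
               density_pA_pF = pk / ts$c_m)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$v_mV), , drop = FALSE]
}

#' Estimate the reversal potential from an I/V table
#'
#' Finds the zero crossing on the positive-voltage limb of the I/V
#' relationship by linear interpolation between the bracketing test
#' voltages.
#'
#' @param iv data frame with columns `v_mV` and `peak_pA` (or the output of
#'   [extract_peak_currents()]).
#' @return Reversal potential in mV.
#' @export
estimate_reversal <- function(iv) {
  v <- iv$v_mV
  i <- iv$peak_pA
  ord <- order(v)
  v <- v[ord]; i <- i[ord]
  sign_change <- which(i[-length(i)] < 0 & i[-1] >= 0)
  if (length(sign_change) == 0)
    stop("no reversal: I/V does not cross zero from inward to outward",
         call. = FALSE)
  j <- tail(sign_change, 1)  # crossing on the positive-voltage limb
  if (i[j + 1] == 0) return(v[j + 1])
  v[j] + (0 - i[j]) * (v[j + 1] - v[j]) / (i[j + 1] - i[j])
}

#' Fit a Boltzmann function to steady-state gating data
#'
#' Bounded trust-region least squares of the two-parameter Boltzmann
#' curve.  Initial midpoint is taken at the interpolated half-maximum
#' crossing; slope starts at 8 mV with bounds (0.5, 30) mV.
#'
#' @param points data frame with columns `v_mV` and `g_over_gmax` (values
#'   in `[0, 1]`); at least 4 points spanning the transition.
#' @param sense `"activation"` or `"inactivation"`.
#' @return A [boltzmann_params()] object with attributes `rss`,
#'   `std_errors` and `fit` (the `nls` object).
#' @export
fit_steady_state_boltzmann <- function(points,
                                       sense = c("activation", "inactivation")) {
  sense <- match.arg(sense)
  v <- points$v_mV
  y <- points$g_over_gmax
  keep <- is.finite(v) & is.finite(y)
  v <- v[keep]; y <- y[keep]
  if (length(v) < 4) stop("need at least 4 points", call. = FALSE)
  if (sd(y) < 1e-6 || diff(range(y)) < 0.05)
    stop("degenerate fit: data do not span the gating transition",
         call. = FALSE)
  s <- if (sense == "activation") -1 else 1
  # initial midpoint: interpolated crossing of y = 0.5
  ord <- order(v)
  v0 <- tryCatch(stats::approx(y[ord], v[ord], xout = 0.5, ties = mean)$y,
                 error = function(e) NA_real_)
  if (!is.finite(v0)) v0 <- v[which.min(abs(y - 0.5))]
  dat <- data.frame(v = v, y = y)
  fit <- tryCatch(
    nls(y ~ 1 / (1 + exp(s * (v - vhalf) / k)), data = dat,
        start = list(vhalf = v0, k = 8), algorithm = "port",
        lower = c(vhalf = min(v) - 50, k = 0.5),
        upper = c(vhalf = max(v) + 50, k = 30),
        control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) stop("Boltzmann fit failed: ", conditionMessage(e),
                             call. = FALSE))
  cf <- coef(fit)
  p <- boltzmann_params(unname(cf["vhalf"]), unname(cf["k"]), sense)
  attr(p, "rss") <- sum(stats::resid(fit)^2)
  attr(p, "std_errors") <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                                    error = function(e) NULL)
  attr(p, "fit") <- fit
  p
}

#' Gating endpoints for an m3h fit at a voltage step
#'
#' The activation variable endpoints are the cube roots of the activation
#' Boltzmann values at the voltage before (`m0`) and after (`m_inf`) the
#' step; the inactivation endpoints are the inactivation Boltzmann values
#' at the same voltages.
#'
#' @param act activation [boltzmann_params()].
#' @param inact inactivation [boltzmann_params()].
#' @param v_before,v_after voltages (mV) preceding and following the step.
#' @return A list with `m0`, `m_inf`, `h0`, `h_inf`.
#' @export
derive_gating_endpoints <- function(act, inact, v_before, v_after) {
  stopifnot(act$sense == "activation", inact$sense == "inactivation")
  list(m0 = boltzmann_curve(v_before, act)^(1 / 3),
       m_inf = boltzmann_curve(v_after, act)^(1 / 3),
       h0 = boltzmann_curve(v_before, inact),
       h_inf = boltzmann_curve(v_after, inact))
}

#' Fit m3h time constants per test voltage
#'
#' Converts each sweep to a conductance trace via the driving force and
#' fits the m3h time course with only `tau_m`, `tau_h` and the offset free;
#' the gating endpoints (from the steady-state Boltzmann fits) and the
#' maximal conductance are held fixed.  Sweeps whose test voltage is within
#' `guard_mv` of the reversal potential are skipped (undefined driving
#' force); non-converging sweeps are flagged and the pipeline continues.
#'
#' @param ts a `trace_set` from an activation-type protocol.
#' @param act,inact steady-state [boltzmann_params()] fits.
#' @param gmax fixed maximal conductance (nS), normally the peak
#'   conductance at the voltage step that yielded the maximum peak current.
#' @param e_na reversal potential (mV).
#' @param guard_mv sweeps with `|v - e_na| < guard_mv` are skipped.
#' @param settle_ms initial interval excluded from the fit (ms).
#' @return Data frame with columns `v_mV`, `tau_m`, `tau_h`, `offset`,
#'   `rss`, `converged`.
#' @export
fit_hh_time_constants <- function(ts, act, inact, gmax, e_na,
                                  guard_mv = 2.5, settle_ms = 0) {
  stopifnot(inherits(ts, "trace_set"))
  v_hold <- ts$protocol$v_hold
  rows <- lapply(sweep_list(ts), function(sw) {
    v <- sw$v_mV[1]
    out <- data.frame(v_mV = v, tau_m = NA_real_, tau_h = NA_real_,
                      offset = NA_real_, rss = NA_real_, converged = FALSE)
    if (abs(v - e_na) < guard_mv) return(out)
    keep <- sw$time_ms >= min(sw$time_ms) + settle_ms
    t <- sw$time_ms[keep]
    g <- conductance_from_current(sw$i_pA[keep], v, e_na)
    ep <- derive_gating_endpoints(act, inact, v_hold, v)
    # initial tau_h from a log-linear regression of the post-peak tail
    ipk <- which.max(g)
    tau_h0 <- 2
    if (ipk < length(g) - 10) {
      tt <- t[ipk:length(g)] - t[ipk]
      gg <- g[ipk:length(g)]
      pos <- gg > max(gg) * 0.01
      if (sum(pos) > 10) {
        sl <- coef(lm(log(gg[pos]) ~ tt[pos]))[2]
        if (is.finite(sl) && sl < 0) tau_h0 <- min(max(-1 / sl, 0.05), 100)
      }
    }
    dat <- data.frame(t = t, g = g, gmax_fix = gmax,
                      m0_fix = ep$m0, minf_fix = ep$m_inf,
                      h0_fix = ep$h0, hinf_fix = ep$h_inf)
    try_fit <- function(tm0, th0) tryCatch(
      nls(g ~ gmax_fix * (minf_fix - (minf_fix - m0_fix) * exp(-t / tau_m))^3 *
            (hinf_fix - (hinf_fix - h0_fix) * exp(-t / tau_h)) + offset,
          data = dat,
          start = list(tau_m = tm0, tau_h = th0, offset = 0),
          algorithm = "port",
          lower = c(tau_m = 0.05, tau_h = 0.05, offset = -10),
          upper = c(tau_m = 100, tau_h = 100, offset = 10),
          control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
      error = function(e) NULL)
    # retry ladder over initial guesses; keep the best-RSS fit
    starts <- unique(rbind(c(0.3, min(max(tau_h0, 0.2), 20)),
                           c(0.3, 2), c(0.1, 0.5), c(1, 10)))
    fit <- NULL
    for (si in seq_len(nrow(starts))) {
      cand <- try_fit(starts[si, 1], starts[si, 2])
      if (!is.null(cand) &&
          (is.null(fit) ||
             sum(stats::resid(cand)^2) < sum(stats::resid(fit)^2)))
        fit <- cand
    }
    if (is.null(fit)) return(out)
    cf <- coef(fit)
    data.frame(v_mV = v, tau_m = unname(cf["tau_m"]),
               tau_h = unname(cf["tau_h"]), offset = unname(cf["offset"]),
               rss = sum(stats::resid(fit)^2), converged = TRUE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$v_mV), , drop = FALSE]
}

#' Fit a double-exponential to the post-peak current decay
#'
#' Identifies the peak (sample of largest magnitude), then fits
#' `-a1 exp(-t/tau1) - a2 exp(-t/tau2)` to the decay segment.  The fast
#' component is labelled `tau1` (`tau1 < tau2` enforced by relabelling).
#' A single-exponential fit of the same segment is performed for model
#' comparison (residual sums of squares and an F test).
#'
#' @param time_ms,i_pA sweep samples; alternatively pass a data frame with
#'   these columns as the first argument.
#' @param settle_ms initial interval excluded before peak search (ms).
#' @return A [decay_params()] object with attributes `rss`, `rss_single`,
#'   `f_statistic`, `p_value` (double- vs single-exponential) and
#'   `prefers_double`.
#' @export
fit_inactivation_double_exp <- function(time_ms, i_pA = NULL,
                                        settle_ms = 0.3) {
  if (is.data.frame(time_ms)) {
    i_pA <- time_ms$i_pA
    time_ms <- time_ms$time_ms
  }
  keep <- time_ms >= min(time_ms) + settle_ms
  t <- time_ms[keep]; i <- i_pA[keep]
  ipk <- which.max(abs(i))
  if (ipk >= length(i) - 10)
    stop("no decay segment after the peak", call. = FALSE)
  td <- t[ipk:length(i)] - t[ipk]
  id <- i[ipk:length(i)]
  a0 <- abs(id[1])
  # tail-based initial slow time constant
  tl <- td > max(td) / 2
  tau2_0 <- 10
  if (sum(tl) > 10 && all(is.finite(log(pmax(abs(id[tl]), 1e-12))))) {
    sl <- coef(lm(log(pmax(abs(id[tl]), 1e-12)) ~ td[tl]))[2]
    if (is.finite(sl) && sl < 0) tau2_0 <- min(max(-1 / sl, 0.1), 100)
  }
  dat <- data.frame(t = td, i = id)
  fit2 <- tryCatch(
    nls(i ~ -a1 * exp(-t / tau1) - a2 * exp(-t / tau2), data = dat,
        start = list(a1 = 0.7 * a0, a2 = 0.3 * a0,
                     tau1 = tau2_0 / 5, tau2 = tau2_0),
        algorithm = "port",
        lower = c(a1 = 0, a2 = 0, tau1 = 0.05, tau2 = 0.05),
        upper = c(a1 = Inf, a2 = Inf, tau1 = 200, tau2 = 200),
        control = stats::nls.control(maxiter = 500, warnOnly = FALSE)),
    error = function(e) stop("double-exponential fit failed: ",
                             conditionMessage(e), call. = FALSE))
  fit1 <- tryCatch(
    nls(i ~ -a1 * exp(-t / tau1), data = dat,
        start = list(a1 = a0, tau1 = tau2_0),
        algorithm = "port", lower = c(a1 = 0, tau1 = 0.05),
        upper = c(a1 = Inf, tau1 = 200)),
    error = function(e) NULL)
  cf <- coef(fit2)
  p <- decay_params(unname(cf["a1"]), unname(cf["a2"]),
                    unname(cf["tau1"]), unname(cf["tau2"]))
  rss2 <- sum(stats::resid(fit2)^2)
  rss1 <- if (is.null(fit1)) NA_real_ else sum(stats::resid(fit1)^2)
  n <- length(id)
  fstat <- pval <- NA_real_
  if (is.finite(rss1) && rss2 > 0) {
    fstat <- ((rss1 - rss2) / 2) / (rss2 / (n - 4))
    pval <- stats::pf(fstat, 2, n - 4, lower.tail = FALSE)
  }
  attr(p, "rss") <- rss2
  attr(p, "rss_single") <- rss1
  attr(p, "f_statistic") <- fstat
  attr(p, "p_value") <- pval
  attr(p, "prefers_double") <- is.finite(pval) && pval < 0.05
  p
}

#' Extract P2/P1 peak ratios from a recovery family
#'
#' Uses the per-sweep pulse windows recorded in the protocol metadata of
#' [simulate_recovery_family()] (or equivalently structured data).
#'
#' @param ts a `trace_set` with protocol `"recovery"`.
#' @param settle_ms initial interval of each pulse excluded (ms).
#' @return Data frame with columns `interval_ms` and `ratio`.
#' @export
extract_recovery_ratios <- function(ts, settle_ms = 0.3) {
  stopifnot(inherits(ts, "trace_set"), ts$protocol$kind == "recovery")
  windows <- ts$protocol$windows
  sw <- sweep_list(ts)
  out <- lapply(seq_along(sw), function(i) {
    s <- sw[[i]]
    w <- windows[[i]]
    peak_in <- function(win) {
      keep <- s$time_ms >= win[1] + settle_ms & s$time_ms <= win[2]
      x <- s$i_pA[keep]
      x[which.max(abs(x))]
    }
    data.frame(interval_ms = w$interval,
               ratio = peak_in(w$p2) / peak_in(w$p1))
  })
  do.call(rbind, out)
}

#' Fit the mono-exponential recovery time course
#'
#' Least-squares fit of `ratio = 1 - exp(-t/tau)`; the half-recovery time
#' is `t_half = tau * ln 2`, exactly.
#'
#' @param ratios data frame with columns `interval_ms` and `ratio`
#'   (at least 5 intervals).
#' @return List with `tau_ms`, `t_half_ms`, `rss` and the `nls` `fit`.
#' @export
fit_recovery_timecourse <- function(ratios) {
  t <- ratios$interval_ms
  y <- ratios$ratio
  if (length(t) < 5) stop("need at least 5 intervals", call. = FALSE)
  half <- tryCatch(stats::approx(y, t, xout = 0.5, ties = mean)$y,
                   error = function(e) NA_real_)
  tau0 <- if (is.finite(half)) half / log(2) else max(t) / 4
  dat <- data.frame(t = t, y = y)
  fit <- tryCatch(
    nls(y ~ 1 - exp(-t / tau), data = dat, start = list(tau = tau0),
        algorithm = "port", lower = c(tau = 0.05), upper = c(tau = 1000),
        control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) stop("recovery fit failed: ", conditionMessage(e),
                             call. = FALSE))
  tau <- unname(coef(fit)["tau"])
  list(tau_ms = tau, t_half_ms = tau * log(2),
       rss = sum(stats::resid(fit)^2), fit = fit)
}

#' Translate the voltage axis of a (voltage, value) table
#'
#' Used to overlay time-constant or gating curves after correcting for a
#' shift in steady-state inactivation between conditions; values are
#' untouched.
#'
#' @param table data frame whose first column (or a column named `v_mV`)
#'   holds voltages in mV.
#' @param shift shift in mV added to the voltages.
#' @return The table with shifted voltages.
#' @export
apply_voltage_shift <- function(table, shift) {
  col <- if ("v_mV" %in% names(table)) "v_mV" else names(table)[1]
  table[[col]] <- table[[col]] + shift
  table
}

#' Full steady-state analysis of an activation family
#'
#' Runs the activation pipeline: peak extraction, reversal estimation,
#' conversion to chord conductance, per-cell normalization to the maximum
#' (G/Gmax) and the activation Boltzmann fit.
#'
#' @param ts a `trace_set` from the activation protocol.
#' @param guard_mv voltages within this margin of the reversal potential
#'   are excluded from the conductance curve (singular driving force).
#' @return List with `iv`, `e_na`, `gmax` (nS), `peak_density_pA_pF`
#'   (magnitude of the largest density), `boltzmann`
#'   ([boltzmann_params()]), and the `g_over_gmax` table.
#' @export
analyze_activation_family <- function(ts, guard_mv = 2.5) {
  iv <- extract_peak_currents(ts)
  e_na <- estimate_reversal(iv)
  use <- abs(iv$v_mV - e_na) >= guard_mv & iv$v_mV < e_na
  g <- conductance_from_current(iv$peak_pA[use], iv$v_mV[use], e_na)
  gmax <- max(g)
  pts <- data.frame(v_mV = iv$v_mV[use], g_over_gmax = g / gmax)
  bz <- fit_steady_state_boltzmann(pts, "activation")
  list(iv = iv, e_na = e_na, gmax = gmax,
       peak_density_pA_pF = max(abs(iv$density_pA_pF)),
       boltzmann = bz, g_over_gmax = pts)
}

#' Full steady-state analysis of an inactivation family
#'
#' Normalizes test-pulse peak currents to the maximum elicited current and
#' fits the inactivation Boltzmann curve against the conditioning voltage.
#'
#' @param ts a `trace_set` from the inactivation protocol.
#' @return List with `availability` table and `boltzmann`
#'   ([boltzmann_params()]).
#' @export
analyze_inactivation_family <- function(ts) {
  iv <- extract_peak_currents(ts)
  avail <- abs(iv$peak_pA) / max(abs(iv$peak_pA))
  pts <- data.frame(v_mV = iv$v_mV, g_over_gmax = avail)
  bz <- fit_steady_state_boltzmann(pts, "inactivation")
  list(availability = pts, boltzmann = bz)
}

#' Combined gating analysis of one simulated or recorded cell
#'
#' Convenience wrapper running the activation, inactivation and recovery
#' analyses and deriving the effective gating charges from the fitted
#' slope factors.
#'
#' @param act_ts,inact_ts,rec_ts `trace_set`s for the three protocols
#'   (`rec_ts` may be `NULL`).
#' @param temperature absolute temperature (K) for the charge calculation.
#' @return An object of class `gating_fit` collecting the fitted
#'   parameters; its `t_half_ms` always equals `recovery_tau_ms * ln 2`.
#' @export
analyze_ephys_cell <- function(act_ts, inact_ts, rec_ts = NULL,
                               temperature = 295.15) {
  act <- analyze_activation_family(act_ts)
  inact <- analyze_inactivation_family(inact_ts)
  rec <- if (!is.null(rec_ts))
    fit_recovery_timecourse(extract_recovery_ratios(rec_ts))
  else NULL
  structure(list(
    act = act$boltzmann,
    inact = inact$boltzmann,
    e_na_mV = act$e_na,
    gmax_nS = act$gmax,
    peak_density_pA_pF = act$peak_density_pA_pF,
    recovery_tau_ms = if (is.null(rec)) NA_real_ else rec$tau_ms,
    t_half_ms = if (is.null(rec)) NA_real_ else rec$t_half_ms,
    z_act = charge_from_slope(act$boltzmann$k, temperature),
    z_inact = charge_from_slope(inact$boltzmann$k, temperature)
  ), class = "gating_fit")
}

#' @export
print.gating_fit <- function(x, ...) {
  cat("Gating analysis\n")
  cat(sprintf("  activation:   vhalf %.2f mV, k %.2f mV (z %.2f)\n",
              x$act$vhalf, x$act$k, x$z_act))
  cat(sprintf("  inactivation: vhalf %.2f mV, k %.2f mV (z %.2f)\n",
              x$inact$vhalf, x$inact$k, x$z_inact))
  cat(sprintf("  e_na %.2f mV, gmax %.2f nS, peak density %.1f pA/pF\n",
              x$e_na_mV, x$gmax_nS, x$peak_density_pA_pF))
  if (is.finite(x$recovery_tau_ms))
    cat(sprintf("  recovery: tau %.2f ms, t_half %.2f ms\n",
                x$recovery_tau_ms, x$t_half_ms))
  invisible(x)
}
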