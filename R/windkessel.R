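## Three-element Windkessel (RCR) outlet models, first-principles calibration
## to a physiological pressure window, and the 0D exchange contract used by
## the flow solver. SI units: Pa, m^3/s, s.

#' Three-element Windkessel parameters for one outlet
#' @param Rp proximal (characteristic) resistance, Pa s/m^3.
#' @param C compliance, m^3/Pa.
#' @param Rd distal resistance, Pa s/m^3.
#' @param P_ref reference (venous) pressure, Pa; pressures are gauge by
#'   default.
#' @return object of class `wk_params`.
#' @export
wk_params <- function(Rp, C, Rd, P_ref = 0) {
  if (Rp <= 0 || Rd <= 0 || C <= 0) stop("Rp, Rd, C must be positive")
  structure(list(Rp = Rp, C = C, Rd = Rd, P_ref = P_ref),
            class = "wk_params")
}

#' One backward-Euler step of the RCR model
#'
#' State equation `C dP_d/dt = Q - (P_d - P_ref)/Rd`; outlet pressure
#' `P = P_d + Q Rp` is returned for the 3D solver's traction boundary
#' condition.
#'
#' @param wk `wk_params`.
#' @param P_d distal (stored) pressure, Pa.
#' @param Q outlet flow for the new time level, m^3/s.
#' @param dt time step, s (> 0).
#' @return list `P_d` (updated), `P` (outlet pressure).
#' @export
rcr_step <- function(wk, P_d, Q, dt) {
  if (dt <= 0) stop("dt must be positive")
  a <- dt / (wk$Rd * wk$C)
  P_d_new <- (P_d + dt / wk$C * Q + a * wk$P_ref) / (1 + a)
  list(P_d = P_d_new, P = P_d_new + Q * wk$Rp)
}

#' RCR input impedance at angular frequency omega
#' @param wk `wk_params`.
#' @param omega angular frequency, rad/s.
#' @return complex impedance `Rp + Rd / (1 + i omega Rd C)`.
#' @export
rcr_impedance <- function(wk, omega) {
  wk$Rp + wk$Rd / (1 + 1i * omega * wk$Rd * wk$C)
}

#' Simulate an RCR model driven by a flow waveform
#' @param wk `wk_params`.
#' @param Q_fun function(t) -> flow m^3/s.
#' @param dt step, s.
#' @param t_end end time, s.
#' @param P_d0 initial distal pressure, Pa.
#' @return data.frame `t`, `Q`, `P_d`, `P`.
#' @export
rcr_simulate <- function(wk, Q_fun, dt, t_end, P_d0 = 0) {
  t <- seq(dt, t_end, by = dt)
  n <- length(t)
  P_d <- numeric(n); P <- numeric(n); Q <- Q_fun(t)
  pd <- P_d0
  for (i in seq_len(n)) {
    st <- rcr_step(wk, pd, Q[i], dt)
    pd <- st$P_d; P_d[i] <- pd; P[i] <- st$P
  }
  data.frame(t = t, Q = Q, P_d = P_d, P = P)
}

#' Calibrate the four-outlet Windkessel bank
#'
#' Total peripheral resistance is the target mean pressure over the mean
#' inflow; it is split across outlets inversely to the desired flow
#' fractions (three arch branches, descending aorta). The proximal fraction
#' of each outlet's resistance is characteristic-impedance sized. The total
#' compliance (split proportionally to flow fraction, so all outlets share
#' one time constant) is tuned by bisection on a lumped whole-model
#' simulation until the cyclically converged pulse pressure matches the
#' target window.
#'
#' @param waveform `flow_waveform` (see [make_waveform()]).
#' @param mean_pressure_mmHg target mean arterial pressure.
#' @param splits flow fractions per outlet, summing to 1 (default 5/5/5/85%).
#' @param pressure_window_mmHg target (diastolic, systolic) window.
#' @param rp_fraction proximal share of each outlet's resistance.
#' @return object of class `wk_bank`: list of `wk_params` (named
#'   `branch1..3`, `desc`), `splits`, achieved `P_min`, `P_max` (mmHg) and
#'   the steady-cycle initial distal pressure `P_d_cyc`.
#' @export
calibrate_windkessel <- function(waveform, mean_pressure_mmHg = 100,
                                 splits = c(branch1 = 0.05, branch2 = 0.05,
                                            branch3 = 0.05, desc = 0.85),
                                 pressure_window_mmHg = c(80, 120),
                                 rp_fraction = 0.06) {
  if (abs(sum(splits) - 1) > 1e-9)
    stop("calibration error: flow splits must sum to 1")
  if (any(splits <= 0)) stop("calibration error: splits must be positive")
  Q_mean <- waveform$SV * waveform$HR / 60      # m^3/s
  P_mean <- mmHg_to_Pa(mean_pressure_mmHg)
  R_tot <- P_mean / Q_mean
  win <- mmHg_to_Pa(pressure_window_mmHg)
  if (diff(win) <= 0 || P_mean <= win[1] || P_mean >= win[2])
    stop("calibration error: infeasible pressure window")

  lumped_pp <- function(C_tot) {
    wk <- wk_params(rp_fraction * R_tot, C_tot, (1 - rp_fraction) * R_tot)
    dt <- waveform$T / 400
    # analytic periodic initial condition would do; a short burn-in is robust
    sim <- rcr_simulate(wk, waveform$Q_fun, dt, 12 * waveform$T,
                        P_d0 = P_mean)
    last <- sim$t > max(sim$t) - waveform$T + dt / 2
    c(pp = max(sim$P[last]) - min(sim$P[last]),
      lo = min(sim$P[last]), hi = max(sim$P[last]),
      pd_end = sim$P_d[nrow(sim)])
  }
  # The mean is fixed by R_tot; size the compliance so the systolic peak sits
  # at the upper window edge. The proximal spike Q_peak * Rp bounds the peak
  # from below even at infinite compliance: if that floor exceeds the window,
  # shrink the proximal fraction until the target is attainable.
  repeat {
    floor_hi <- lumped_pp(1e-6)["hi"]
    if (floor_hi < win[2] - 1) break
    rp_fraction <- rp_fraction / 2
    if (rp_fraction < 1e-4)
      stop("calibration error: pressure window unattainable")
  }
  f <- function(logC) lumped_pp(exp(logC))["hi"] - win[2]
  sol <- uniroot(f, lower = log(1e-10), upper = log(1e-6), tol = 1e-7)
  C_tot <- exp(sol$root)
  ach <- lumped_pp(C_tot)
  if (ach[["lo"]] < win[1] - 1e-6)
    stop("calibration error: diastolic pressure falls below the window")
  bank <- lapply(seq_along(splits), function(i)
    wk_params(Rp = rp_fraction * R_tot / unname(splits[i]),
              C = C_tot * unname(splits[i]),
              Rd = (1 - rp_fraction) * R_tot / unname(splits[i])))
  names(bank) <- names(splits)
  structure(list(outlets = bank, splits = splits,
                 rp_fraction = rp_fraction,
                 R_total = R_tot, C_total = C_tot,
                 P_min_mmHg = ach[["lo"]] / 133.3224,
                 P_max_mmHg = ach[["hi"]] / 133.3224,
                 P_d_cyc = ach[["pd_end"]]),
            class = "wk_bank")
}

#' @export
print.wk_bank <- function(x, ...) {
  cat("<wk_bank> ", length(x$outlets), " outlets; R_total=",
      signif(x$R_total, 4), " Pa s/m^3, C_total=", signif(x$C_total, 4),
      " m^3/Pa\n  converged pressure ", round(x$P_min_mmHg, 1), "-",
      round(x$P_max_mmHg, 1), " mmHg\n", sep = "")
  invisible(x)
}

#' Advance all outlet Windkessel models one step (exchange contract)
#'
#' Order-independent across outlets; the flows passed in and the pressures
#' returned are exchanged exactly.
#'
#' @param bank `wk_bank`.
#' @param P_d named/ordered vector of distal pressures, Pa.
#' @param Q vector of outlet flows, m^3/s (one per outlet).
#' @param dt step, s.
#' @return list `P_d` (updated vector), `P` (outlet pressures, Pa).
#' @export
couple_windkessel <- function(bank, P_d, Q, dt) {
  n <- length(bank$outlets)
  if (length(Q) != n)
    stop("configuration error: ", length(Q), " flows for ", n, " outlets")
  P <- numeric(n); Pd <- numeric(n)
  for (i in seq_len(n)) {
    st <- rcr_step(bank$outlets[[i]], P_d[i], Q[i], dt)
    Pd[i] <- st$P_d; P[i] <- st$P
  }
  list(P_d = Pd, P = P)
}

#' Pulsatile inlet flow waveform
#'
#' Single-peaked half-sine systolic ejection over `systolic_fraction` of the
#' cycle, zero (optionally slightly negative) diastolic flow; the integral
#' over one period equals the stroke volume.
#'
#' @param HR heart rate, beats/min.
#' @param SV stroke volume, m^3 (default 53 ml).
#' @param systolic_fraction fraction of the period spent ejecting.
#' @param reverse_fraction fraction of SV regurgitated in early diastole
#'   (half-sine lobe over 0.1 T), default 0.
#' @return object of class `flow_waveform`: `HR`, `SV`, `T`, `Q_fun(t)`
#'   (periodic), `Q_peak`, `systolic_fraction`.
#' @export
make_waveform <- function(HR = 75, SV = 53e-6, systolic_fraction = 0.35,
                          reverse_fraction = 0) {
  if (HR <= 0 || SV <= 0) stop("HR and SV must be positive")
  if (systolic_fraction <= 0 || systolic_fraction >= 1)
    stop("systolic_fraction must lie in (0, 1)")
  T <- 60 / HR
  t_sys <- systolic_fraction * T
  SV_fwd <- SV * (1 + reverse_fraction)
  Q_peak <- pi * SV_fwd / (2 * t_sys)
  t_rev <- 0.1 * T
  Q_rev_peak <- if (reverse_fraction > 0)
    pi * SV * reverse_fraction / (2 * t_rev) else 0
  Q_fun <- function(t) {
    tm <- t %% T
    q <- ifelse(tm < t_sys, Q_peak * sin(pi * tm / t_sys), 0)
    if (Q_rev_peak > 0)
      q <- q - ifelse(tm >= t_sys & tm < t_sys + t_rev,
                      Q_rev_peak * sin(pi * (tm - t_sys) / t_rev), 0)
    q
  }
  structure(list(HR = HR, SV = SV, T = T, Q_fun = Q_fun, Q_peak = Q_peak,
                 systolic_fraction = systolic_fraction,
                 reverse_fraction = reverse_fraction,
                 t_peak = t_sys / 2),
            class = "flow_waveform")
}

#' Cyclic convergence check on outlet pressure traces
#'
#' Converged when the maximum over outlets of the cycle-to-cycle relative
#' pressure-trace difference (L-infinity, normalized by the trace range)
#' drops below `tol`.
#'
#' @param traces list per outlet of numeric matrices (cycles x samples) or a
#'   single such matrix.
#' @param tol relative tolerance (default 1%).
#' @return list `converged`, `cycle` (first converged cycle index, NA if
#'   none), `history` (per-cycle max difference).
#' @export
check_cyclic_convergence <- function(traces, tol = 0.01) {
  if (is.matrix(traces)) traces <- list(traces)
  n_cyc <- nrow(traces[[1]])
  if (n_cyc < 2) stop("need at least two completed cycles")
  hist <- rep(NA_real_, n_cyc)
  for (k in 2:n_cyc) {
    d <- vapply(traces, function(m) {
      rng <- max(abs(m[k, ])) + 1e-300
      max(abs(m[k, ] - m[k - 1, ])) / rng
    }, numeric(1))
    hist[k] <- max(d)
  }
  idx <- which(hist < tol)[1]
  list(converged = !is.na(idx), cycle = if (is.na(idx)) NA_integer_ else idx,
       history = hist)
}
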