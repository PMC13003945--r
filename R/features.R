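#' Jump height from take-off velocity
#'
#' `h = v^2 / (2 g)` with g = 9.81 m/s^2, v the upward COM velocity at
#' take-off.
#'
#' @param v_takeoff take-off COM velocity, m/s (must be > 0).
#' @return jump height in metres.
#' @export
jump_height <- function(v_takeoff) {
  if (!is.numeric(v_takeoff) || any(v_takeoff <= 0))
    stop("no upward velocity at take-off")
  v_takeoff^2 / (2 * 9.81)
}

#' Reactive strength index
#'
#' Jump height divided by ground contact time (m/s).
#'
#' @param h jump height (m).
#' @param ct ground contact time (s), > 0.
#' @return RSI in m/s.
#' @export
reactive_strength_index <- function(h, ct) {
  if (any(ct <= 0)) stop("contact time must be positive")
  h / ct
}

# indices of a signal's samples inside [t0, t1]
phase_idx <- function(times, phase) {
  idx <- which(times >= phase[1] - 1e-9 & times <= phase[2] + 1e-9)
  if (length(idx) < 2) stop("phase contains too few samples")
  idx
}

trapz <- function(t, y) sum((y[-1] + y[-length(y)]) / 2 * diff(t))

#' Mass-normalized vertical impulse over a phase
#'
#' Trapezoidal integral of the vertical GRF over the phase, divided by body
#' mass (N s / kg).
#'
#' @param fz single-channel `sampled_signal` of vertical GRF (N).
#' @param phase `c(t_start, t_end)` seconds.
#' @param mass body mass (kg).
#' @return impulse in N s / kg.
#' @export
phase_impulse <- function(fz, phase, mass) {
  tt <- signal_times(fz)
  idx <- phase_idx(tt, phase)
  trapz(tt[idx], fz$values[idx, 1]) / mass
}

#' GRF summaries: mean/peak per phase, RFD, force at zero COM velocity,
#' vertical stiffness, synchronicity
#'
#' All force quantities are normalized by body mass. Definitions:
#' \itemize{
#'   \item mean/peak: over the given phase (N/kg);
#'   \item `f_zero_vel`: vertical GRF at the COM-minimum instant (N/kg);
#'   \item `stiffness`: peak eccentric GRF / |eccentric COM displacement|
#'     (N/m/kg);
#'   \item `rfd`: peak eccentric GRF divided by the time from ground contact
#'     to that peak (N/s/kg) — a documented interpretation, the alternative
#'     max-slope definition is available via `rfd_method = "max_slope"`;
#'   \item `synchro`: |t(peak GRF during contact) - t(COM minimum)| as a
#'     percentage of contact time — a documented interpretation of the
#'     peak-force/zero-velocity timing-offset concept.
#' }
#'
#' @param fz single-channel `sampled_signal`, vertical GRF (N).
#' @param events `trial_events` with contact, COM-min and take-off times.
#' @param com_z vertical COM `sampled_signal` (m), for displacements.
#' @param mass body mass (kg).
#' @param rfd_method `"peak_over_time"` (default) or `"max_slope"`.
#' @return named list of scalars.
#' @export
grf_summaries <- function(fz, events, com_z, mass,
                          rfd_method = c("peak_over_time", "max_slope")) {
  rfd_method <- match.arg(rfd_method)
  tt <- signal_times(fz)
  ecc <- c(events$t_contact, events$t_com_min)
  con <- c(events$t_com_min, events$t_takeoff)
  i_ecc <- phase_idx(tt, ecc); i_con <- phase_idx(tt, con)
  i_all <- phase_idx(tt, c(events$t_contact, events$t_takeoff))
  f <- fz$values[, 1] / mass

  peak_ecc <- max(f[i_ecc])
  t_peak_ecc <- tt[i_ecc[which.max(f[i_ecc])]]
  t_peak_all <- tt[i_all[which.max(f[i_all])]]

  tz <- signal_times(com_z)
  z_at <- stats::approxfun(tz, com_z$values[, 1])
  ecc_disp <- abs(z_at(events$t_com_min) - z_at(events$t_contact))
  con_disp <- abs(z_at(events$t_takeoff) - z_at(events$t_com_min))
  if (ecc_disp < 1e-9) stop("zero eccentric COM displacement: stiffness undefined")

  rfd <- if (rfd_method == "peak_over_time") {
    peak_ecc / max(t_peak_ecc - events$t_contact, 1e-6)
  } else {
    max(diff(f[i_ecc]) * fz$rate_hz)
  }

  list(
    mean_grf_ecc = mean(f[i_ecc]), peak_grf_ecc = peak_ecc,
    mean_grf_con = mean(f[i_con]), peak_grf_con = max(f[i_con]),
    f_zero_vel = stats::approx(tt, f, xout = events$t_com_min)$y,
    stiffness = peak_ecc / ecc_disp,
    rfd = rfd,
    synchro = abs(t_peak_all - events$t_com_min) /
      (events$t_takeoff - events$t_contact) * 100,
    ecc_disp = ecc_disp, con_disp = con_disp
  )
}

#' COM power and per-phase COM work
#'
#' Power `P(t) = Fz(t) v(t) / mass` (W/kg); work is the trapezoidal integral
#' of power over the phase (J/kg). On a well-formed drop jump the eccentric
#' work is negative and the concentric work positive; violations are flagged
#' with a warning, not an error.
#'
#' @param fz vertical GRF `sampled_signal` (N).
#' @param com_velocity vertical COM velocity `sampled_signal` (m/s), on the
#'   same timebase as `fz`.
#' @param phase `c(t0, t1)` seconds.
#' @param mass body mass (kg).
#' @param phase_label optional `"ecc"`/`"con"` for the sign check.
#' @return list `power` (vector, W/kg over the phase) and `work` (J/kg).
#' @export
com_power_work <- function(fz, com_velocity, phase, mass, phase_label = NULL) {
  if (nrow(fz$values) != nrow(com_velocity$values) ||
      abs(fz$rate_hz - com_velocity$rate_hz) > 1e-9)
    stop("force and COM velocity series must share a timebase")
  tt <- signal_times(fz)
  idx <- phase_idx(tt, phase)
  p <- fz$values[idx, 1] * com_velocity$values[idx, 1] / mass
  w <- trapz(tt[idx], p)
  if (!is.null(phase_label)) {
    if (phase_label == "ecc" && w > 1e-6)
      warning("eccentric COM work is positive")
    if (phase_label == "con" && w < -1e-6)
      warning("concentric COM work is negative")
  }
  list(power = p, work = w)
}
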