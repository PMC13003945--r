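#' Default motion profile for a synthetic drop jump
#'
#' The defaults describe the task the package targets: a drop from a 0.3 m
#' box, ground contact around 0.22 s, a 0.33 m jump, with landing posture and
#' small frontal/transverse excursions typical of collegiate athletes.
#'
#' @param drop_height box height in metres.
#' @param contact_time prescribed ground contact duration (s), in (0.05, 0.6).
#' @param jump_height prescribed jump height (m), from take-off COM velocity.
#' @param crouch_pre crouch parameter in [0.05, 0.6] at the instant of ground
#'   contact (0 = fully extended, 1 = deepest squat of the posture family).
#' @param pulse_exponent exponent p of the contact force pulse
#'   `Fz = m K sin(pi tau)^p`; p = 1 gives the sharp onset/offset seen on
#'   force plates.
#' @param theta_shank_max,theta_thigh_max,theta_trunk_max sagittal segment
#'   inclinations (degrees from vertical) at full crouch.
#' @param knee_valgus_dev_m amplitude of the in-trial lateral knee excursion.
#' @param hip_rot_deg,shank_rot_deg amplitudes of axial-rotation excursions.
#' @param trunk_sway_m lateral trunk sway amplitude.
#' @param baseline_knee_dev_m,baseline_rot_deg,baseline_lean_deg constant
#'   (participant-level) posture offsets, giving non-degenerate angles at
#'   ground contact.
#' @return named list of profile parameters.
#' @export
dj_profile <- function(drop_height = 0.3, contact_time = 0.22,
                       jump_height = 0.33, crouch_pre = 0.12,
                       pulse_exponent = 1,
                       theta_shank_max = 25, theta_thigh_max = 80,
                       theta_trunk_max = 40,
                       knee_valgus_dev_m = 0.015, hip_rot_deg = 7,
                       shank_rot_deg = 5, trunk_sway_m = 0.02,
                       baseline_knee_dev_m = 0.01, baseline_rot_deg = 5,
                       baseline_lean_deg = 2) {
  as.list(environment())
}

# ---- kinematic chain -------------------------------------------------------
#
# Vectorised construction of the full marker set for n frames, given crouch
# values `cr` (vector) and wiggle series. Ankles on the floor (z = ankle
# height); the caller shifts everything vertically for airborne phases.

chain_geometry <- function(height_m) {
  list(
    ankle_h = 0.039 * height_m,
    shank = 0.246 * height_m,
    thigh = 0.245 * height_m,
    trunk = 0.288 * height_m,
    head = 0.182 * height_m,
    foot_len = 0.152 * height_m,
    stance_y = 0.12,       # ankle lateral half-spacing (one foot per plate)
    knee_y = 0.105,
    hip_y = 0.09,
    asis_y = 0.12,
    mal_y = 0.04,          # malleolar half-width
    epi_y = 0.05           # epicondylar half-width
  )
}

# wig: list of numeric vectors length n:
#   valgus (m, lateral knee deviation, +ve = outward), hip_rot (deg),
#   shank_rot (deg), sway (m, trunk lateral), lean (deg, extra trunk lean)
## segment inclinations vs crouch: near-sqrt so that the COM drop (which
## scales with 1 - cos(theta) ~ theta^2) is close to linear in the crouch
## parameter; a linear COM map keeps joint-angle accelerations bounded at
## the contact boundaries, where the crouch is solved from the COM height.
crouch_angle <- function(cr, theta_max) {
  eps <- 0.06
  theta_max * (sqrt(cr + eps) - sqrt(eps)) / (sqrt(1 + eps) - sqrt(eps))
}

## the crouch parameter covers two smoothly blended domains: cr > 0 flexes
## the chain (squat), cr < 0 plantarflexes the feet (heel raise, pivoting
## about the toes), which lifts the COM above the flat-foot standing height
## as in a real toe-off. softplus split keeps the blend C-infinity.
crouch_split <- function(cr, plantar_max_deg = 35, k = 0.06) {
  z <- cr / k
  cpos <- k * (pmax(z, 0) + log1p(exp(-abs(z))))
  list(cpos = cpos, phi_deg = plantar_max_deg * (cpos - cr))
}

make_marker_frames <- function(cr, wig, geom, profile) {
  n <- length(cr)
  d2r <- pi / 180
  cs <- crouch_split(cr)
  th_s <- crouch_angle(cs$cpos, profile$theta_shank_max) * d2r
  th_t <- crouch_angle(cs$cpos, profile$theta_thigh_max) * d2r
  th_tr <- (crouch_angle(cs$cpos, profile$theta_trunk_max) + wig$lean) * d2r
  phi <- cs$phi_deg * d2r

  mk <- list()
  toe_rel <- 0.75 * geom$foot_len
  rel_ax <- geom$ankle_h - 0.02        # ankle height above the sole plane
  for (side in c("L", "R")) {
    sgn <- if (side == "L") 1 else -1
    ay <- sgn * geom$stance_y
    # foot pivots about the toe contact point by the plantar angle phi
    A <- cbind(toe_rel - (toe_rel * cos(phi) - rel_ax * sin(phi)),
               rep(ay, n),
               0.02 + toe_rel * sin(phi) + rel_ax * cos(phi))
    # knee: lateral target = nominal knee_y + outward valgus deviation
    ky <- sgn * (geom$knee_y + wig$valgus)
    dy1 <- ky - ay
    s1 <- sqrt(pmax(0, 1 - (dy1 / geom$shank)^2))
    K <- A + geom$shank * cbind(s1 * sin(th_s), dy1 / geom$shank, s1 * cos(th_s))
    hy <- sgn * geom$hip_y
    dy2 <- hy - ky
    s2 <- sqrt(pmax(0, 1 - (dy2 / geom$thigh)^2))
    H <- K + geom$thigh * cbind(-s2 * sin(th_t), dy2 / geom$thigh, s2 * cos(th_t))
    mk[[paste0("ankle_", side)]] <- A
    mk[[paste0("knee_", side)]] <- K
    mk[[paste0("hip_", side)]] <- H
  }
  mid_hip <- (mk$hip_L + mk$hip_R) / 2
  tr_dir <- cbind(sin(th_tr), wig$sway / geom$trunk, cos(th_tr))
  tr_dir <- tr_dir / sqrt(rowSums(tr_dir^2))
  C7 <- mid_hip + geom$trunk * tr_dir
  VERTEX <- mid_hip + (geom$trunk + geom$head) * tr_dir

  # pelvis frame axes: y toward the left hip, z along trunk
  yp <- mk$hip_L - mk$hip_R
  yp <- yp / sqrt(rowSums(yp^2))
  zp <- tr_dir
  xp <- cbind(yp[, 2] * zp[, 3] - yp[, 3] * zp[, 2],
              yp[, 3] * zp[, 1] - yp[, 1] * zp[, 3],
              yp[, 1] * zp[, 2] - yp[, 2] * zp[, 1])
  xp <- xp / sqrt(rowSums(xp^2))

  out <- list()
  for (side in c("L", "R")) {
    sgn <- if (side == "L") 1 else -1
    A <- mk[[paste0("ankle_", side)]]
    K <- mk[[paste0("knee_", side)]]
    H <- mk[[paste0("hip_", side)]]
    # heel and toe pivot with the foot about the toe contact point
    ay <- sgn * geom$stance_y
    out[[paste0("HEEL_", side)]] <-
      cbind(toe_rel - geom$foot_len * cos(phi), rep(ay, n),
            0.02 + geom$foot_len * sin(phi))
    out[[paste0("TOE_", side)]] <-
      cbind(rep(toe_rel, n), rep(ay, n), rep(0.02, n))
    # malleoli: rotated about the shank long axis by the axial wiggle
    sh_axis <- (K - A) / geom$shank
    ml0 <- cbind(0, rep(sgn, n), 0)
    rot <- sgn * (profile$baseline_rot_deg + wig$shank_rot) * d2r
    ml <- rotate_about_rows(ml0, sh_axis, rot)
    out[[paste0("LMAL_", side)]] <- A + geom$mal_y * ml
    out[[paste0("MMAL_", side)]] <- A - geom$mal_y * ml
    # femoral epicondyles about the thigh long axis
    th_axis <- (H - K) / geom$thigh
    er <- sgn * (profile$baseline_rot_deg + wig$hip_rot) * d2r
    el <- rotate_about_rows(ml0, th_axis, er)
    out[[paste0("LEPI_", side)]] <- K + geom$epi_y * el
    out[[paste0("MEPI_", side)]] <- K - geom$epi_y * el
    # greater trochanter: lateral to the hip centre; the analyzer inverts
    # this with the 0.11 x inter-ASIS medial shift, so keep them consistent
    out[[paste0("TROCH_", side)]] <- H + sgn * 0.11 * (2 * geom$asis_y) * yp
    out[[paste0("ASIS_", side)]] <-
      mid_hip + 0.06 * xp + sgn * geom$asis_y * yp + 0.05 * zp
  }
  out$C7 <- C7
  out$VERTEX <- VERTEX
  out$STERN <- mid_hip + 0.9 * geom$trunk * tr_dir + 0.09 * xp
  out
}

# Smooth clamp of the crouch parameter to [lo, hi]: exact identity away
# from the bounds, C-infinity saturation of width k at them.
soft_clamp <- function(x, lo = -0.92, hi = 0.97, k = 0.02) {
  z1 <- (x - lo) / k
  x <- lo + k * (pmax(z1, 0) + log1p(exp(-abs(z1))))
  z2 <- (hi - x) / k
  hi - k * (pmax(z2, 0) + log1p(exp(-abs(z2))))
}

# Rodrigues rotation of row-vectors v about row-unit-axes k by angles a.
rotate_about_rows <- function(v, k, a) {
  ca <- cos(a); sa <- sin(a)
  kv <- cbind(k[, 2] * v[, 3] - k[, 3] * v[, 2],
              k[, 3] * v[, 1] - k[, 1] * v[, 3],
              k[, 1] * v[, 2] - k[, 2] * v[, 1])
  kdv <- rowSums(k * v)
  v * ca + kv * sa + k * kdv * (1 - ca)
}

# Vertical whole-body COM of the chain at crouch values cr (ankles on floor).
chain_com_z <- function(cr, wig, geom, profile, model) {
  mkr <- make_marker_frames(cr, wig, geom, profile)
  whole_body_com(mkr, model)$com[, 3]
}

const_wig <- function(n, profile) {
  list(valgus = rep(profile$baseline_knee_dev_m, n),
       hip_rot = rep(0, n), shank_rot = rep(0, n),
       sway = rep(0, n), lean = rep(profile$baseline_lean_deg, n))
}

# ---- force pulse -----------------------------------------------------------

# Contact-phase COM acceleration a(u) = -g + K sin(pi u/T)^p, with K chosen
# so the net velocity change over [0, T] equals dv. Returns functions and the
# numerically integrated velocity/position on a fine grid.
contact_pulse <- function(T, dv, p, g = 9.81, ngrid = 4000) {
  sbar <- stats::integrate(function(x) sin(pi * x)^p, 0, 1,
                           rel.tol = 1e-10)$value
  K <- (dv + g * T) / (T * sbar)
  u <- seq(0, T, length.out = ngrid)
  a <- -g + K * sin(pi * u / T)^p
  du <- u[2] - u[1]
  v <- cumsum(c(0, (a[-1] + a[-ngrid]) / 2 * du))
  z <- cumsum(c(0, (v[-1] + v[-ngrid]) / 2 * du))
  list(K = K, u = u, a = a, v = v, z = z,
       afun = function(t) -g + K * sin(pi * pmin(pmax(t / T, 0), 1))^p)
}

# ---- trial generator -------------------------------------------------------

#' Generate a dynamically consistent synthetic drop-jump trial
#'
#' Constructs a drop jump whose vertical ground reaction force satisfies
#' `Fz(t) = m (a_com(t) + g)` at every sample by design: the COM trajectory
#' is prescribed (ballistic drop, a `sin^p` force pulse during contact,
#' ballistic flight, landing pulse, quiet stance) and the marker kinematics
#' are solved so the segment-model COM tracks the prescribed COM. During
#' contact the feet stay planted and the crouch parameter is obtained by
#' inverting the posture-family COM map; in the air the posture relaxes and
#' the chain is translated ballistically.
#'
#' @param profile motion profile from [dj_profile()].
#' @param anthropometry list with `height_m` and `mass_kg`.
#' @param noise_sd additive i.i.d. Gaussian noise SD on marker coordinates
#'   (metres). Force channels get noise with SD `400 * noise_sd` N.
#' @param seed integer RNG seed (required when `noise_sd > 0`).
#' @param marker_rate_hz,force_rate_hz sampling rates.
#' @return list of class `dj_trial` with elements `recording`
#'   (markers + forces + anthropometry) and `truth` (a `dj_truth` list with
#'   contact time, jump height, RSI, phase boundaries, COM trajectory,
#'   sagittal joint-angle profiles, per-phase ROM truth, COM work truth and
#'   the quasi-static ankle moment implied by the generated CoP).
#' @export
generate_trial <- function(profile = dj_profile(),
                           anthropometry = list(height_m = 1.74, mass_kg = 79),
                           noise_sd = 0, seed = 1L,
                           marker_rate_hz = 250, force_rate_hz = 1000) {
  g <- 9.81
  hgt <- anthropometry$height_m; m <- anthropometry$mass_kg
  if (is.null(hgt) || is.null(m) || m <= 0 || hgt <= 0)
    stop("anthropometry must supply positive height_m and mass_kg")
  if (profile$drop_height <= 0) stop("drop height must be positive")
  if (profile$contact_time <= 0.05 || profile$contact_time >= 0.6)
    stop("contact_time must lie in (0.05, 0.6) s")
  if (profile$jump_height <= 0) stop("jump_height must be positive")
  leg_len <- (0.246 + 0.245) * hgt
  geom <- chain_geometry(hgt)
  model <- reduced_segment_model()

  # posture-family COM map f(c) and its inverse (monotone decreasing)
  cgrid <- seq(-0.95, 0.99, length.out = 200)
  fz <- chain_com_z(cgrid, const_wig(length(cgrid), profile), geom, profile,
                    model)
  if (any(diff(fz) >= 0)) stop("posture COM map is not monotone")
  finv <- stats::splinefun(rev(fz), rev(cgrid), method = "hyman")
  fwd <- stats::splinefun(cgrid, fz, method = "hyman")

  c_pre <- profile$crouch_pre
  z_c <- fwd(c_pre)
  fprime <- function(cc) fwd(cc, deriv = 1)
  descent_max <- fwd(c_pre) - fz[length(fz)]
  if (profile$drop_height > leg_len)
    stop("descent deeper than leg length is not physical")

  T <- profile$contact_time
  v_in <- sqrt(2 * g * profile$drop_height)
  v_out <- sqrt(2 * g * profile$jump_height)
  t_gc <- sqrt(2 * profile$drop_height / g)
  pulse <- contact_pulse(T, v_in + v_out, profile$pulse_exponent, g)
  z_contact <- z_c + (-v_in) * pulse$u + pulse$z
  if (z_c - min(z_contact) > 0.95 * descent_max)
    stop("prescribed impulse requires a descent deeper than the posture ",
         "family allows; reduce drop/contact time or crouch_pre")
  t_to <- t_gc + T
  z_to <- z_contact[length(z_contact)]

  # COM minimum: v = 0 inside contact
  vfun <- stats::approxfun(pulse$u, -v_in + pulse$v)
  t_com_min <- t_gc + stats::uniroot(vfun, c(1e-6, T - 1e-6))$root

  # flight: posture relaxes from the take-off crouch with its exit rate
  zfun_contact <- stats::splinefun(pulse$u, z_contact)
  c_exit <- finv(z_to)
  dc_exit <- (finv(zfun_contact(T)) - finv(zfun_contact(T - 2e-3))) / 2e-3
  # zero slope-discontinuity AND zero curvature at take-off, back to the
  # take-off posture well before landing; soft-clamped so the posture never
  # slams into its bounds (a hard clamp is a velocity corner that rings
  # through the zero-phase filter back into the contact window)
  tau_r <- 0.025
  c_flight <- function(u) soft_clamp(
    c_exit + dc_exit * u * exp(-(u / tau_r)^2))
  z_flight <- function(u) z_to + v_out * u - g * u^2 / 2
  ankle_air <- function(u) z_flight(u) - fwd(c_flight(u))
  t_fl_guess <- 2 * v_out / g
  t_fl <- stats::uniroot(ankle_air, c(0.6 * t_fl_guess, 1.4 * t_fl_guess))$root
  t_land <- t_to + t_fl
  v_land <- v_out - g * t_fl
  z_land <- z_flight(t_fl)

  # landing pulse: bring the COM to rest
  T_l <- 0.20
  pulse2 <- contact_pulse(T_l, -v_land, profile$pulse_exponent, g)
  z_landing <- z_land + v_land * pulse2$u + pulse2$z
  t_settle <- t_land + T_l
  z_settle <- z_landing[length(z_landing)]
  t_end <- t_settle + 0.08

  # --- continuous-time COM / force description -----------------------------
  com_z_at <- function(t) {
    out <- numeric(length(t))
    drop <- t < t_gc
    out[drop] <- z_c + profile$drop_height - g * t[drop]^2 / 2
    con <- t >= t_gc & t <= t_to
    out[con] <- zfun_contact(t[con] - t_gc)
    fl <- t > t_to & t < t_land
    out[fl] <- z_flight(t[fl] - t_to)
    zl <- stats::splinefun(pulse2$u, z_landing)
    ld <- t >= t_land & t <= t_settle
    out[ld] <- zl(t[ld] - t_land)
    st <- t > t_settle
    out[st] <- z_settle
    out
  }
  fz_total_at <- function(t) {
    out <- numeric(length(t))
    con <- t >= t_gc & t <= t_to
    out[con] <- m * (pulse$afun(t[con] - t_gc) + g)
    ld <- t >= t_land & t <= t_settle
    out[ld] <- m * (pulse2$afun(t[ld] - t_land) + g)
    out[t > t_settle] <- m * g
    out
  }

  # --- marker kinematics at the marker rate --------------------------------
  tm <- seq(0, t_end, by = 1 / marker_rate_hz)
  nM <- length(tm)
  zcm <- com_z_at(tm)
  crouch <- numeric(nM)
  shift <- numeric(nM)
  for (i in seq_len(nM)) {
    t <- tm[i]
    if (t >= t_gc && t <= t_to) {
      crouch[i] <- finv(zcm[i]); shift[i] <- 0
    } else if (t < t_gc) {
      # anticipatory flexion: C1 continuation of the contact-side crouch
      # rate, so joint-angle series have no velocity kink at touch-down
      dc_gc <- -v_in / fprime(c_pre)
      u <- t - t_gc
      crouch[i] <- soft_clamp(c_pre + dc_gc * u * exp(-(u / 0.025)^2))
      shift[i] <- zcm[i] - fwd(crouch[i])
    } else if (t > t_to && t < t_land) {
      crouch[i] <- c_flight(t - t_to)
      shift[i] <- zcm[i] - fwd(crouch[i])
    } else if (t >= t_land && t <= t_settle) {
      crouch[i] <- finv(pmin(max(fz[-length(fz)]), pmax(min(fz), zcm[i])))
      shift[i] <- zcm[i] - fwd(crouch[i])
    } else {
      crouch[i] <- finv(pmin(max(fz[-length(fz)]), pmax(min(fz), zcm[i])))
      shift[i] <- zcm[i] - fwd(crouch[i])
    }
  }
  # in-contact wiggle window (C1 at the boundaries) for both contacts
  prog <- function(t, t0, Tdur) pmin(pmax((t - t0) / Tdur, 0), 1)
  w1 <- sin(pi * prog(tm, t_gc, T))^2
  w2 <- sin(pi * prog(tm, t_land, T_l))^2
  wwin <- pmax(w1, w2)
  phs <- 2 * pi * prog(tm, t_gc, T)
  wig <- list(
    valgus = profile$baseline_knee_dev_m + profile$knee_valgus_dev_m * wwin,
    hip_rot = profile$hip_rot_deg * wwin * sin(phs / 2),
    shank_rot = profile$shank_rot_deg * wwin,
    sway = profile$trunk_sway_m * wwin * sin(phs),
    lean = profile$baseline_lean_deg + 0 * tm
  )
  markers <- make_marker_frames(crouch, wig, geom, profile)
  markers <- lapply(markers, function(mk) mk + cbind(0, 0, shift))

  # --- forces at the force rate --------------------------------------------
  tf <- seq(0, t_end, by = 1 / force_rate_hz)
  fz_tot <- fz_total_at(tf)
  asym <- 0.02
  fz1 <- fz_tot * (0.5 + asym); fz2 <- fz_tot * (0.5 - asym)
  tauc <- prog(tf, t_gc, T)
  fx1 <- 0.03 * fz1 * sin(2 * pi * tauc); fx2 <- -0.03 * fz2 * sin(2 * pi * tauc)
  fy1 <- 0.02 * fz1 * sin(pi * tauc); fy2 <- -0.02 * fz2 * sin(pi * tauc)
  copx <- -0.02 + 0.10 * tauc                 # heel-to-forefoot progression
  cop1 <- cbind(copx, rep(geom$stance_y, length(tf)))
  cop2 <- cbind(copx, rep(-geom$stance_y, length(tf)))

  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    markers <- lapply(markers, function(mk)
      mk + matrix(stats::rnorm(length(mk), 0, noise_sd), nrow(mk)))
    fn <- 400 * noise_sd
    for (nm in c("fz1", "fz2", "fx1", "fx2", "fy1", "fy2"))
      assign(nm, get(nm) + stats::rnorm(length(tf), 0, fn))
    fz1 <- pmax(fz1, 0); fz2 <- pmax(fz2, 0)
  }

  forces <- sampled_signal(
    cbind(fz1 = fz1, fz2 = fz2, fx1 = fx1, fx2 = fx2, fy1 = fy1, fy2 = fy2,
          copx1 = cop1[, 1], copy1 = cop1[, 2],
          copx2 = cop2[, 1], copy2 = cop2[, 2]),
    force_rate_hz, 0)

  # --- ground truth ---------------------------------------------------------
  d2r <- pi / 180
  cs <- crouch_split(crouch)
  th_s <- crouch_angle(cs$cpos, profile$theta_shank_max)
  th_t <- crouch_angle(cs$cpos, profile$theta_thigh_max)
  th_tr <- crouch_angle(cs$cpos, profile$theta_trunk_max) +
    profile$baseline_lean_deg
  truth_angles <- list(
    hip = -(th_t + th_tr),     # flexion negative (matches the SCS convention)
    knee = -(th_s + th_t),
    ankle = th_s - cs$phi_deg  # shank lean dorsiflexes, heel raise plantarflexes
  )
  phase_rom <- function(a, t0, t1) {
    idx <- tm >= t0 - 1e-9 & tm <= t1 + 1e-9
    max(a[idx]) - min(a[idx])
  }
  rom_truth <- lapply(truth_angles, function(a)
    c(ecc = phase_rom(a, t_gc, t_com_min), con = phase_rom(a, t_com_min, t_to)))

  # quasi-static ankle moment about the lab y axis (foot is at rest during
  # contact), left leg, in the analyzer's convention: moment applied by the
  # shank on the foot balances the plate force about the ankle,
  # M_y = (r_cop - r_ankle) x F |_y = r_z Fx - r_x Fz with r_z = -ankle_h
  ankle_pos <- c(0, geom$ankle_h)
  fz_leg <- fz_total_at(tf) * 0.52          # left plate carries 0.5 + asym
  fx_leg <- 0.03 * fz_leg * sin(2 * pi * prog(tf, t_gc, T))
  m_ankle_y <- (copx - ankle_pos[1]) * fz_leg + ankle_pos[2] * fx_leg
  m_ankle_y[tf < t_gc | tf > t_to] <- 0

  # truth COM work per phase from the analytic force and velocity
  v_at <- function(t) {
    out <- numeric(length(t))
    drop <- t < t_gc; out[drop] <- -g * t[drop]
    con <- t >= t_gc & t <= t_to
    vv <- stats::approxfun(pulse$u, -v_in + pulse$v, rule = 2)
    out[con] <- vv(t[con] - t_gc)
    fl <- t > t_to & t < t_land; out[fl] <- v_out - g * (t[fl] - t_to)
    out
  }
  work_phase <- function(t0, t1) {
    tt <- seq(t0, t1, length.out = 2000)
    p <- fz_total_at(tt) * v_at(tt) / m
    sum((p[-1] + p[-length(p)]) / 2 * diff(tt))
  }
  imp_phase <- function(t0, t1) {
    tt <- seq(t0, t1, length.out = 2000)
    f <- fz_total_at(tt) / m
    sum((f[-1] + f[-length(f)]) / 2 * diff(tt))
  }

  truth <- structure(list(
    contact_time_s = T,
    jump_height_m = profile$jump_height,
    rsi = profile$jump_height / T,
    t_contact = t_gc, t_com_min = t_com_min, t_takeoff = t_to,
    t_landing = t_land,
    flight_time_s = t_fl,
    v_takeoff = v_out, v_contact = -v_in,
    body_mass_kg = m, height_m = hgt,
    com_z = zcm, com_times = tm,
    peak_fz_n_kg = pulse$K + 0,
    joint_angle_profiles = truth_angles,
    rom_truth = rom_truth,
    ankle_moment_y = m_ankle_y,
    com_work_ecc = work_phase(t_gc, t_com_min),
    com_work_con = work_phase(t_com_min, t_to),
    impulse_ecc = imp_phase(t_gc, t_com_min),
    impulse_con = imp_phase(t_com_min, t_to),
    ecc_disp = abs(com_z_at(t_com_min) - z_c),
    con_disp = abs(z_to - com_z_at(t_com_min))
  ), class = "dj_truth")

  structure(list(
    recording = list(markers = markers, marker_rate_hz = marker_rate_hz,
                     forces = forces,
                     anthropometry = list(height_m = hgt, mass_kg = m)),
    truth = truth
  ), class = "dj_trial")
}

#' @export
print.dj_trial <- function(x, ...) {
  cat(sprintf(paste0("<dj_trial: mass %.1f kg, contact %.3f s, ",
                     "jump %.3f m, rsi %.2f m/s>\n"),
              x$truth$body_mass_kg, x$truth$contact_time_s,
              x$truth$jump_height_m, x$truth$rsi))
  invisible(x)
}
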