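# Bottom-up Newton-Euler inverse dynamics for the lower limbs.

# Angular velocity (lab frame, rad/s) of a list of rotation matrices by
# central differences: omega_skew = Rdot %*% t(R).
frame_angular_velocity <- function(frames, rate_hz) {
  n <- length(frames)
  dt <- 1 / rate_hz
  w <- matrix(0, n, 3)
  for (i in 2:(n - 1)) {
    Rd <- (frames[[i + 1]] - frames[[i - 1]]) / (2 * dt)
    S <- Rd %*% t(frames[[i]])
    w[i, ] <- c(S[3, 2], S[1, 3], S[2, 1])
  }
  w[1, ] <- w[2, ]; w[n, ] <- w[n - 1, ]
  w
}

#' Bottom-up inverse dynamics of the lower limbs
#'
#' Newton-Euler recursion per limb (foot, shank, thigh) from the measured
#' plate force and centre of pressure: net joint forces and moments at the
#' ankle, knee and hip, joint powers `P = M . (omega_distal -
#' omega_proximal)`, and per-phase joint work (trapezoidal integral of
#' power, normalized by body mass). Segment inertia is modelled as a sphere
#' of radius `gyration_ratio * length` about the segment COM (the transverse
#' radius of gyration; axial asymmetry is ignored, which is adequate for
#' near-planar motion). One plate per foot is required.
#'
#' @param markers filtered marker trajectories (named list of n x 3, metres)
#'   on the marker timebase.
#' @param rate_hz marker sampling rate.
#' @param plate_forces list per side (`L`, `R`), each a data.frame/list with
#'   vectors `fx`, `fy`, `fz` (N) and `copx`, `copy` (m), already
#'   interpolated to the marker timebase.
#' @param mass body mass (kg).
#' @param model reduced segment model.
#' @return list with `moments` (per side/joint n x 3, N m), `powers`
#'   (per side/joint vector, W/kg), `omega` and a `work()` helper is left to
#'   the caller via [phase_joint_work()].
#' @export
inverse_dynamics <- function(markers, rate_hz, plate_forces, mass,
                             model = reduced_segment_model()) {
  if (!all(c("L", "R") %in% names(plate_forces)))
    stop("per-plate force assignment (one plate per foot) is required")
  jc <- joint_centres(markers)
  fr <- segment_frames(markers)
  wb <- whole_body_com(markers, model)
  n <- nrow(jc$ankle_L)
  g <- 9.81

  seg_par <- function(name) {
    s <- Filter(function(x) x$name == name, model)[[1]]
    s
  }
  seg_len <- function(p, d) mean(sqrt(rowSums((p - d)^2)))

  acc <- function(x) apply(x, 2, central_derivative, rate_hz = rate_hz, order = 2)
  omdot <- function(w) apply(w, 2, central_derivative, rate_hz = rate_hz, order = 1)
  crossm <- function(a, b) cross3(a, b)

  out <- list(moments = list(), powers = list(), forces = list(),
              omega = list())
  for (side in c("L", "R")) {
    pf <- plate_forces[[side]]
    Fext <- cbind(pf$fx, pf$fy, pf$fz)
    cop <- cbind(pf$copx, pf$copy, 0)
    segs <- list(
      foot = list(par = seg_par(paste0("foot_", side)),
                  prox = jc[[paste0("ankle_", side)]],
                  a = jc[[paste0("heel_", side)]],
                  b = jc[[paste0("toe_", side)]],
                  frames = fr[[paste0("foot_", side)]]),
      shank = list(par = seg_par(paste0("shank_", side)),
                   prox = jc[[paste0("knee_", side)]],
                   a = jc[[paste0("knee_", side)]],
                   b = jc[[paste0("ankle_", side)]],
                   frames = fr[[paste0("shank_", side)]]),
      thigh = list(par = seg_par(paste0("thigh_", side)),
                   prox = jc[[paste0("hip_", side)]],
                   a = jc[[paste0("hip_", side)]],
                   b = jc[[paste0("knee_", side)]],
                   frames = fr[[paste0("thigh_", side)]])
    )
    F_dist <- Fext; M_dist <- matrix(0, n, 3); r_dist <- cop
    om_prev <- NULL
    for (joint in c("ankle", "knee", "hip")) {
      seg <- segs[[c(ankle = "foot", knee = "shank", hip = "thigh")[[joint]]]]
      ms <- seg$par$mass_fraction * mass
      com <- seg$a + seg$par$com_ratio * (seg$b - seg$a)
      L <- seg_len(seg$a, seg$b)
      I <- ms * (seg$par$gyration_ratio * L)^2
      a_com <- acc(com)
      om <- frame_angular_velocity(seg$frames, rate_hz)
      al <- omdot(om)
      W <- matrix(c(0, 0, -ms * g), n, 3, byrow = TRUE)
      F_prox <- ms * a_com - F_dist - W
      M_prox <- I * al + crossm(om, I * om) -
        crossm(r_dist - com, F_dist) - M_dist -
        crossm(seg$prox - com, F_prox)
      out$moments[[paste0(joint, "_", side)]] <- M_prox
      out$forces[[paste0(joint, "_", side)]] <- F_prox
      out$omega[[paste0(joint, "_", side)]] <- om
      # next segment sees the reaction at this joint
      F_dist <- -F_prox; M_dist <- -M_prox; r_dist <- seg$prox
    }
    # joint powers: moment on the distal segment times relative angular
    # velocity of distal w.r.t. proximal; pelvis omega for the hip
    om_pel <- frame_angular_velocity(fr$pelvis, rate_hz)
    om_foot <- out$omega[[paste0("ankle_", side)]]
    om_shank <- out$omega[[paste0("knee_", side)]]
    om_thigh <- out$omega[[paste0("hip_", side)]]
    out$powers[[paste0("ankle_", side)]] <-
      rowSums(out$moments[[paste0("ankle_", side)]] * (om_foot - om_shank)) / mass
    out$powers[[paste0("knee_", side)]] <-
      rowSums(out$moments[[paste0("knee_", side)]] * (om_shank - om_thigh)) / mass
    out$powers[[paste0("hip_", side)]] <-
      rowSums(out$moments[[paste0("hip_", side)]] * (om_thigh - om_pel)) / mass
  }
  out$times <- (seq_len(n) - 1) / rate_hz
  out$rate_hz <- rate_hz
  out
}

#' Per-phase joint work from an inverse-dynamics result
#'
#' Trapezoidal integral of joint power over the phase, summed over both
#' sides (so the result is whole-body work at that joint, J/kg).
#'
#' @param dyn result of [inverse_dynamics()].
#' @param joint one of `"ankle"`, `"knee"`, `"hip"`.
#' @param phase `c(t0, t1)` seconds on the marker timebase.
#' @return work in J/kg.
#' @export
phase_joint_work <- function(dyn, joint, phase) {
  idx <- which(dyn$times >= phase[1] - 1e-9 & dyn$times <= phase[2] + 1e-9)
  if (length(idx) < 2) stop("phase contains too few samples")
  tt <- dyn$times[idx]
  sum(vapply(c("L", "R"), function(side) {
    p <- dyn$powers[[paste0(joint, "_", side)]][idx]
    sum((p[-1] + p[-length(p)]) / 2 * diff(tt))
  }, numeric(1)))
}
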