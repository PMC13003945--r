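#' Catalogue of feature-table columns
#'
#' The 3 outcomes plus the 44 predictors carried by the default feature
#' table, with units and phase tags (`@GC` = at initial ground contact,
#' `ECC`/`CON` = eccentric/concentric phase, `WC` = whole contact). The six
#' joint-work variables (`work_hip/knee/ankle x ECC/CON`) are computed by the
#' pipeline as auxiliary columns; they are excluded from the default
#' 44-predictor set so that the predictor inventory (5 global kinetics +
#' 9 contact angles + 8 per-phase temporal/GRF + 4 per-phase COM + 18 ROMs)
#' totals exactly 44.
#'
#' @param include_joint_work include the six joint-work columns.
#' @return data.frame with `name`, `unit`, `phase`, `role`.
#' @export
feature_catalog <- function(include_joint_work = FALSE) {
  row <- function(name, unit, phase, role = "predictor")
    data.frame(name = name, unit = unit, phase = phase, role = role)
  out <- rbind(
    row("ct", "s", "WC", "outcome"),
    row("ht", "m", "WC", "outcome"),
    row("rsi", "m/s", "WC", "outcome"),
    row("stiffness", "N/m/kg", "ECC"),
    row("rfd", "N/s/kg", "ECC"),
    row("synchro", "%", "WC"),
    row("imp_ratio", "unitless", "WC"),
    row("f_zero_vel", "N/kg", "WC"),
    row("hip_ef_gc", "deg", "@GC"), row("hip_ab_gc", "deg", "@GC"),
    row("hip_rot_gc", "deg", "@GC"),
    row("knee_ef_gc", "deg", "@GC"), row("knee_vv_gc", "deg", "@GC"),
    row("knee_rot_gc", "deg", "@GC"),
    row("ankle_pd_gc", "deg", "@GC"), row("ankle_ei_gc", "deg", "@GC"),
    row("ankle_ab_gc", "deg", "@GC")
  )
  for (ph in c("ecc", "con")) {
    PH <- toupper(ph)
    out <- rbind(out,
      row(paste0("ct_", ph), "s", PH),
      row(paste0("imp_", ph), "Ns/kg", PH),
      row(paste0("grf_mean_", ph), "N/kg", PH),
      row(paste0("grf_peak_", ph), "N/kg", PH),
      row(paste0("disp_", ph), "m", PH),
      row(paste0("work_", ph), "J/kg", PH),
      row(paste0("hip_rom_ef_", ph), "deg", PH),
      row(paste0("hip_rom_ab_", ph), "deg", PH),
      row(paste0("hip_rom_rot_", ph), "deg", PH),
      row(paste0("knee_rom_ef_", ph), "deg", PH),
      row(paste0("knee_rom_vv_", ph), "deg", PH),
      row(paste0("knee_rom_rot_", ph), "deg", PH),
      row(paste0("ankle_rom_pd_", ph), "deg", PH),
      row(paste0("ankle_rom_ei_", ph), "deg", PH),
      row(paste0("ankle_rom_ab_", ph), "deg", PH))
  }
  if (include_joint_work) {
    for (ph in c("ecc", "con")) for (j in c("hip", "knee", "ankle"))
      out <- rbind(out, row(paste0("work_", j, "_", ph), "J/kg", toupper(ph),
                            "auxiliary"))
  }
  rownames(out) <- NULL
  out
}

#' Analyze one drop-jump trial
#'
#' Full single-trial pipeline: zero-lag filtering of markers and forces,
#' event detection on the (by default raw) summed vertical GRF, phase
#' segmentation at the COM minimum, outcome computation, and the phase-tagged
#' kinetic/kinematic feature set. Events are detected on the unfiltered
#' force because zero-phase filtering smears the sharp force onset across
#' the threshold; all amplitude features use the filtered channels.
#'
#' @param recording list with `markers` (named list of n x 3), `marker_rate_hz`,
#'   `forces` (`sampled_signal` with channels fz1, fz2, fx1, fx2, fy1, fy2,
#'   copx1, copy1, copx2, copy2) and `anthropometry` (`height_m`, `mass_kg`).
#' @param cutoff_hz low-pass cutoff for markers and forces (Hz).
#' @param threshold_n event threshold on vertical GRF (N).
#' @param filter_force_for_events detect events on the filtered force
#'   instead of the raw force.
#' @param compute_joint_work run inverse dynamics and add joint-work columns.
#' @return list: `features` (named numeric vector), `events`, `com_z`
#'   (1000 Hz `sampled_signal`), `angles`, `dyn` (if requested).
#' @export
analyze_trial <- function(recording, cutoff_hz = 20, threshold_n = 20,
                          filter_force_for_events = FALSE,
                          compute_joint_work = TRUE) {
  m <- recording$anthropometry$mass_kg
  fs_m <- recording$marker_rate_hz
  fmk <- lapply(recording$markers, function(x)
    butterworth_zero_lag(sampled_signal(x, fs_m), cutoff_hz)$values)
  forces_f <- butterworth_zero_lag(recording$forces, cutoff_hz)
  # CoP channels: keep the raw (already smooth) values to avoid ringing
  cop_cols <- grep("^cop", colnames(recording$forces$values))
  forces_f$values[, cop_cols] <- recording$forces$values[, cop_cols]

  fzsum_raw <- sampled_signal(
    recording$forces$values[, "fz1"] + recording$forces$values[, "fz2"],
    recording$forces$rate_hz, recording$forces$t0)
  fzsum_f <- sampled_signal(
    forces_f$values[, "fz1"] + forces_f$values[, "fz2"],
    forces_f$rate_hz, forces_f$t0)
  ev <- detect_contact_takeoff(
    if (filter_force_for_events) fzsum_f else fzsum_raw,
    threshold_n = threshold_n)

  # COM at marker rate, then cubic-resampled to the force timebase
  wb <- whole_body_com(fmk, rate_hz = fs_m)
  com250 <- sampled_signal(wb$com[, 3], fs_m, 0)
  al <- align_and_resample(com250, fzsum_f)
  com1k <- al$markers
  fz1k <- al$forces
  ev <- segment_phases(com1k, ev)

  v1k <- central_derivative(com1k)
  tt <- signal_times(v1k)
  i_to <- which.min(abs(tt - ev$t_takeoff))
  v_to <- v1k$values[i_to, 1]
  ht <- jump_height(v_to)
  rsi <- reactive_strength_index(ht, ev$contact_time)

  ecc <- c(ev$t_contact, ev$t_com_min)
  con <- c(ev$t_com_min, ev$t_takeoff)
  imp_ecc <- phase_impulse(fz1k, ecc, m)
  imp_con <- phase_impulse(fz1k, con, m)
  gs <- grf_summaries(fz1k, ev, com1k, m)
  w_ecc <- com_power_work(fz1k, v1k, ecc, m, "ecc")$work
  w_con <- com_power_work(fz1k, v1k, con, m, "con")$work

  ang <- joint_angle_series(fmk, fs_m)
  ang_at <- function(series, t)
    apply(series, 2, function(a) stats::approx(ang$times, a, xout = t)$y)
  bilat <- function(joint) bilateral_mean(ang[[paste0(joint, "_L")]],
                                          ang[[paste0(joint, "_R")]])
  hip <- bilat("hip"); knee <- bilat("knee"); ankle <- bilat("ankle")
  gc <- list(hip = ang_at(hip, ev$t_contact),
             knee = ang_at(knee, ev$t_contact),
             ankle = ang_at(ankle, ev$t_contact))
  roms <- function(series, phase) range_of_motion(series, ang$times, phase)

  f <- c(
    ct = ev$contact_time, ht = ht, rsi = rsi,
    stiffness = gs$stiffness, rfd = gs$rfd, synchro = gs$synchro,
    imp_ratio = imp_ecc / imp_con, f_zero_vel = gs$f_zero_vel,
    hip_ef_gc = gc$hip[1], hip_ab_gc = gc$hip[2], hip_rot_gc = gc$hip[3],
    knee_ef_gc = gc$knee[1], knee_vv_gc = gc$knee[2],
    knee_rot_gc = gc$knee[3],
    ankle_pd_gc = gc$ankle[1], ankle_ei_gc = gc$ankle[2],
    ankle_ab_gc = gc$ankle[3]
  )
  for (ph in c("ecc", "con")) {
    phase <- if (ph == "ecc") ecc else con
    rh <- roms(hip, phase); rk <- roms(knee, phase); ra <- roms(ankle, phase)
    f <- c(f, stats::setNames(c(
      diff(phase),
      if (ph == "ecc") imp_ecc else imp_con,
      gs[[paste0("mean_grf_", ph)]], gs[[paste0("peak_grf_", ph)]],
      gs[[paste0(ph, "_disp")]],
      if (ph == "ecc") w_ecc else w_con,
      rh[1], rh[2], rh[3], rk[1], rk[2], rk[3], ra[1], ra[2], ra[3]),
      paste0(c("ct_", "imp_", "grf_mean_", "grf_peak_", "disp_", "work_",
               "hip_rom_ef_", "hip_rom_ab_", "hip_rom_rot_",
               "knee_rom_ef_", "knee_rom_vv_", "knee_rom_rot_",
               "ankle_rom_pd_", "ankle_rom_ei_", "ankle_rom_ab_"), ph)))
  }

  dyn <- NULL
  if (compute_joint_work) {
    tfm <- (seq_len(nrow(fmk[[1]])) - 1) / fs_m
    tf <- signal_times(forces_f)
    interp <- function(ch) stats::approx(tf, forces_f$values[, ch],
                                         xout = tfm, rule = 2)$y
    plate_forces <- list(
      L = list(fx = interp("fx1"), fy = interp("fy1"), fz = interp("fz1"),
               copx = interp("copx1"), copy = interp("copy1")),
      R = list(fx = interp("fx2"), fy = interp("fy2"), fz = interp("fz2"),
               copx = interp("copx2"), copy = interp("copy2"))
    )
    dyn <- inverse_dynamics(fmk, fs_m, plate_forces, m)
    for (ph in c("ecc", "con")) {
      phase <- if (ph == "ecc") ecc else con
      for (j in c("hip", "knee", "ankle"))
        f[[paste0("work_", j, "_", ph)]] <- phase_joint_work(dyn, j, phase)
    }
  }

  list(features = f, events = ev, com_z = com1k, com_velocity = v1k,
       angles = ang, dyn = dyn, fz = fz1k)
}

#' Assemble the participant-level feature table
#'
#' Combines per-participant trial analyses into the participants x
#' (44 predictors + 3 outcomes) table. Each participant contributes the mean
#' of their valid trials by default, or the trial with maximal RSI with
#' `aggregate = "best"`; the aggregation is permutation-invariant across
#' trial order.
#'
#' @param analyses list (per participant) of lists (per trial) of
#'   [analyze_trial()] results, or of bare feature vectors.
#' @param aggregate `"mean"` or `"best"` (max-RSI trial).
#' @param include_joint_work keep the auxiliary joint-work columns.
#' @return data.frame (one row per participant) with attribute `units`.
#' @export
assemble_feature_table <- function(analyses, aggregate = c("mean", "best"),
                                   include_joint_work = FALSE) {
  aggregate <- match.arg(aggregate)
  cat_df <- feature_catalog(include_joint_work)
  wanted <- cat_df$name
  rows <- lapply(seq_along(analyses), function(i) {
    trials <- analyses[[i]]
    if (!is.null(trials$features)) trials <- list(trials)
    fx <- lapply(trials, function(tr)
      if (is.list(tr) && !is.null(tr$features)) tr$features else unlist(tr))
    for (v in fx) {
      miss <- setdiff(wanted, names(v))
      if (length(miss))
        stop("participant ", i, " is missing variables: ",
             paste(miss, collapse = ", "))
    }
    mat <- do.call(rbind, lapply(fx, function(v) v[wanted]))
    if (aggregate == "mean") colMeans(mat) else mat[which.max(mat[, "rsi"]), ]
  })
  tab <- as.data.frame(do.call(rbind, rows))
  names(tab) <- wanted
  if (anyNA(tab)) stop("feature table contains missing cells")
  attr(tab, "units") <- stats::setNames(cat_df$unit, cat_df$name)
  attr(tab, "phases") <- stats::setNames(cat_df$phase, cat_df$name)
  tab
}
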