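#' Detect ground contact, take-off and landing from vertical GRF
#'
#' Threshold crossings on the summed vertical force of both plates:
#' contact is the first upward crossing, take-off the next downward crossing,
#' landing the following upward crossing. A crossing only counts if the
#' signal stays beyond the threshold for at least `min_dwell_s` (spike
#' rejection; the level itself is the conventional 20 N).
#'
#' @param fz_total a single-channel `sampled_signal` of summed vertical GRF
#'   (N), or a numeric vector with `rate_hz`.
#' @param threshold_n force threshold in newtons.
#' @param min_dwell_s minimum time the force must stay across the threshold.
#' @param rate_hz sampling rate when `fz_total` is a bare vector.
#' @return list `t_contact`, `t_takeoff`, `t_landing` (seconds, at
#'   force-plate resolution), plus `contact_time` and `flight_time`.
#' @export
detect_contact_takeoff <- function(fz_total, threshold_n = 20,
                                   min_dwell_s = 0.005, rate_hz = NULL) {
  if (inherits(fz_total, "sampled_signal")) {
    x <- fz_total$values[, 1]; fs <- fz_total$rate_hz; t0 <- fz_total$t0
  } else {
    if (is.null(rate_hz)) stop("rate_hz required for a bare vector")
    x <- as.numeric(fz_total); fs <- rate_hz; t0 <- 0
  }
  above <- x >= threshold_n
  dwell <- max(1L, round(min_dwell_s * fs))
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- runs$lengths >= dwell
  # state sequence after dwell filtering: merge short blips into neighbours
  st <- runs$values[keep]
  sx <- starts[keep]
  ups <- sx[st == TRUE]
  downs <- sx[st == FALSE]
  if (length(ups) < 1)
    stop("incomplete trial: no ground contact (no upward crossing)")
  t_contact <- t0 + (ups[1] - 1) / fs
  after <- downs[downs > ups[1]]
  if (length(after) < 1)
    stop("incomplete trial: no take-off (no downward crossing after contact)")
  t_takeoff <- t0 + (after[1] - 1) / fs
  ups2 <- ups[ups > after[1]]
  if (length(ups2) < 1)
    stop("incomplete trial: no landing (no upward crossing after take-off)")
  t_landing <- t0 + (ups2[1] - 1) / fs
  list(t_contact = t_contact, t_takeoff = t_takeoff, t_landing = t_landing,
       contact_time = t_takeoff - t_contact,
       flight_time = t_landing - t_takeoff)
}

#' Split ground contact into eccentric and concentric phases
#'
#' The eccentric phase runs from ground contact to the minimum vertical COM
#' position; the concentric phase from that minimum to take-off. Ties are
#' broken to the earliest sample; a boundary minimum (monotone COM over
#' contact) is accepted with a warning.
#'
#' @param com_z a single-channel `sampled_signal` of vertical COM position.
#' @param events partial event list from [detect_contact_takeoff()].
#' @return `trial_events` list adding `t_com_min`, `ecc_duration`,
#'   `con_duration`.
#' @export
segment_phases <- function(com_z, events) {
  stopifnot(inherits(com_z, "sampled_signal"))
  tt <- signal_times(com_z)
  idx <- which(tt >= events$t_contact - 1e-9 & tt <= events$t_takeoff + 1e-9)
  if (length(idx) < 3)
    stop("com_z does not cover the contact interval")
  z <- com_z$values[idx, 1]
  imin <- idx[which.min(z)]          # which.min takes the earliest tie
  if (imin == idx[1] || imin == idx[length(idx)])
    warning("COM minimum falls on a contact boundary (monotone COM)")
  events$t_com_min <- tt[imin]
  events$ecc_duration <- events$t_com_min - events$t_contact
  events$con_duration <- events$t_takeoff - events$t_com_min
  structure(events, class = "trial_events")
}

#' @export
print.trial_events <- function(x, ...) {
  cat(sprintf(paste0("<trial_events: contact %.3f s, com-min %.3f s, ",
                     "take-off %.3f s, landing %.3f s>\n"),
              x$t_contact, x$t_com_min, x$t_takeoff, x$t_landing))
  invisible(x)
}
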