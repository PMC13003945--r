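#' Fifteen-segment inertial parameter table
#'
#' Standard published body-segment inertial parameters (Dempster-derived, as
#' tabulated by Winter): per-segment mass fraction of total body mass,
#' centre-of-mass position as a fraction of segment length from the proximal
#' end, and radius of gyration about the transverse axis through the segment
#' COM as a fraction of segment length. The trunk is split into pelvis and
#' thorax-abdomen so the model has 15 segments and 14 joints. The table is a
#' replaceable asset: any data frame with the same columns is accepted by the
#' downstream functions.
#'
#' @return data.frame with columns `segment`, `side`, `mass_fraction`,
#'   `com_ratio`, `gyration_ratio`, `proximal`, `distal`.
#' @export
segment_parameter_table <- function() {
  one <- function(seg, side, mf, cr, gr, prox, dist)
    data.frame(segment = seg, side = side, mass_fraction = mf,
               com_ratio = cr, gyration_ratio = gr,
               proximal = prox, distal = dist)
  rbind(
    one("head_neck", "C", 0.081, 0.500, 0.495, "c7", "vertex"),
    one("thorax_abdomen", "C", 0.355, 0.500, 0.430, "mid_hip", "c7"),
    one("pelvis", "C", 0.142, 0.500, 0.310, "mid_hip", "mid_asis"),
    one("upper_arm", "L", 0.028, 0.436, 0.322, "shoulder", "elbow"),
    one("upper_arm", "R", 0.028, 0.436, 0.322, "shoulder", "elbow"),
    one("forearm", "L", 0.016, 0.430, 0.303, "elbow", "wrist"),
    one("forearm", "R", 0.016, 0.430, 0.303, "elbow", "wrist"),
    one("hand", "L", 0.006, 0.506, 0.297, "wrist", "knuckle"),
    one("hand", "R", 0.006, 0.506, 0.297, "wrist", "knuckle"),
    one("thigh", "L", 0.100, 0.433, 0.323, "hip", "knee"),
    one("thigh", "R", 0.100, 0.433, 0.323, "hip", "knee"),
    one("shank", "L", 0.0465, 0.433, 0.302, "knee", "ankle"),
    one("shank", "R", 0.0465, 0.433, 0.302, "knee", "ankle"),
    one("foot", "L", 0.0145, 0.500, 0.475, "heel", "toe"),
    one("foot", "R", 0.0145, 0.500, 0.475, "heel", "toe")
  )
}

#' Reduced segment model for the bundled marker set
#'
#' The capture protocol keeps the hands on the hips, so the upper limbs ride
#' with the trunk; with the reduced lower-limb + trunk marker set the upper
#' body is lumped into a single head-arms-trunk (HAT) segment above the
#' pelvis. The reduced model therefore has 8 segments: 2 feet, 2 shanks,
#' 2 thighs, pelvis, and HAT (thorax-abdomen + head + both arms). Mass
#' fractions are exact sums of the 15-segment table, so they still total 1.
#'
#' HAT and pelvis COMs are placed on the mid-hip to C7 axis at documented
#' ratios (pelvis 0.10, HAT 0.63 of the way up); foot COM at the heel-toe
#' midpoint; thigh/shank COMs at the standard 0.433 proximal ratio.
#'
#' @param full optional replacement 15-segment table (see
#'   [segment_parameter_table()]).
#' @return list of segment definitions used by [whole_body_com()] and
#'   [inverse_dynamics()].
#' @export
reduced_segment_model <- function(full = segment_parameter_table()) {
  mf <- function(seg) sum(full$mass_fraction[full$segment == seg])
  hat <- mf("thorax_abdomen") + mf("head_neck") +
    mf("upper_arm") + mf("forearm") + mf("hand")
  gr <- function(seg) full$gyration_ratio[full$segment == seg][1]
  segs <- list(
    list(name = "foot_L", mass_fraction = mf("foot") / 2, com_ratio = 0.5,
         gyration_ratio = gr("foot"), proximal = "heel_L", distal = "toe_L"),
    list(name = "foot_R", mass_fraction = mf("foot") / 2, com_ratio = 0.5,
         gyration_ratio = gr("foot"), proximal = "heel_R", distal = "toe_R"),
    list(name = "shank_L", mass_fraction = mf("shank") / 2, com_ratio = 0.433,
         gyration_ratio = gr("shank"), proximal = "knee_L", distal = "ankle_L"),
    list(name = "shank_R", mass_fraction = mf("shank") / 2, com_ratio = 0.433,
         gyration_ratio = gr("shank"), proximal = "knee_R", distal = "ankle_R"),
    list(name = "thigh_L", mass_fraction = mf("thigh") / 2, com_ratio = 0.433,
         gyration_ratio = gr("thigh"), proximal = "hip_L", distal = "knee_L"),
    list(name = "thigh_R", mass_fraction = mf("thigh") / 2, com_ratio = 0.433,
         gyration_ratio = gr("thigh"), proximal = "hip_R", distal = "knee_R"),
    list(name = "pelvis", mass_fraction = mf("pelvis"), com_ratio = 0.10,
         gyration_ratio = gr("pelvis"), proximal = "mid_hip", distal = "c7"),
    list(name = "hat", mass_fraction = hat, com_ratio = 0.63,
         gyration_ratio = gr("thorax_abdomen"), proximal = "mid_hip",
         distal = "c7")
  )
  stopifnot(abs(sum(vapply(segs, `[[`, 1, "mass_fraction")) - 1) < 1e-9)
  segs
}

# ---- joint centres from markers -------------------------------------------

#' Joint centres from the bundled marker set
#'
#' Conventions (documented, swappable): ankle = mid-malleolar midpoint;
#' knee = mid-epicondyle midpoint; hip = greater trochanter translated
#' medially by 0.11 x inter-ASIS width. mid_hip is the midpoint of the two
#' hip centres. All conventions act frame-wise on a marker array.
#'
#' @param markers named list of n x 3 matrices (one per marker), metres.
#' @return named list of n x 3 joint-centre trajectories, including the
#'   marker passthroughs needed by the reduced segment model.
#' @export
joint_centres <- function(markers) {
  need <- c("LMAL_L", "MMAL_L", "LMAL_R", "MMAL_R",
            "LEPI_L", "MEPI_L", "LEPI_R", "MEPI_R",
            "TROCH_L", "TROCH_R", "ASIS_L", "ASIS_R",
            "HEEL_L", "TOE_L", "HEEL_R", "TOE_R", "C7")
  miss <- setdiff(need, names(markers))
  if (length(miss)) stop("missing markers: ", paste(miss, collapse = ", "))
  mid <- function(a, b) (markers[[a]] + markers[[b]]) / 2
  asw <- markers$ASIS_R - markers$ASIS_L        # left -> right across pelvis
  hip <- function(side) {
    sgn <- if (side == "L") +1 else -1          # medial = toward midline
    markers[[paste0("TROCH_", side)]] + sgn * 0.11 * asw
  }
  hl <- hip("L"); hr <- hip("R")
  list(
    ankle_L = mid("LMAL_L", "MMAL_L"), ankle_R = mid("LMAL_R", "MMAL_R"),
    knee_L = mid("LEPI_L", "MEPI_L"), knee_R = mid("LEPI_R", "MEPI_R"),
    hip_L = hl, hip_R = hr, mid_hip = (hl + hr) / 2,
    mid_asis = mid("ASIS_L", "ASIS_R"),
    heel_L = markers$HEEL_L, toe_L = markers$TOE_L,
    heel_R = markers$HEEL_R, toe_R = markers$TOE_R,
    c7 = markers$C7
  )
}

#' Whole-body centre of mass
#'
#' Mass-fraction-weighted sum of segment COMs, each segment COM interpolated
#' between its proximal and distal joint centres at the segment's `com_ratio`.
#'
#' @param markers named list of n x 3 marker trajectories (metres).
#' @param model segment model from [reduced_segment_model()].
#' @param rate_hz sampling rate of the marker trajectories.
#' @return list: `com` (n x 3 matrix), `com_z` (a `sampled_signal` of the
#'   vertical component), `segments` (per-segment COM trajectories).
#' @export
whole_body_com <- function(markers, model = reduced_segment_model(),
                           rate_hz = NULL) {
  jc <- joint_centres(markers)
  bad <- vapply(jc, function(m) any(!is.finite(m)), logical(1))
  if (any(bad)) {
    frames <- sort(unique(unlist(lapply(jc[bad], function(m)
      which(rowSums(!is.finite(m)) > 0)))))
    stop("missing/non-finite marker data in frames: ",
         paste(utils::head(frames, 10), collapse = ", "))
  }
  seg_com <- lapply(model, function(s) {
    p <- jc[[s$proximal]]; d <- jc[[s$distal]]
    p + s$com_ratio * (d - p)
  })
  names(seg_com) <- vapply(model, `[[`, "", "name")
  com <- Reduce(`+`, Map(function(s, sc) s$mass_fraction * sc, model, seg_com))
  out <- list(com = com, segments = seg_com)
  if (!is.null(rate_hz))
    out$com_z <- sampled_signal(com[, 3], rate_hz, 0, channels = "com_z")
  out
}

# ---- rotations and Cardan angles ------------------------------------------

rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3)
rot_y <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3)
rot_z <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3)

axis_rot <- function(axis, a) switch(axis, x = rot_x(a), y = rot_y(a), z = rot_z(a))

#' Compose a rotation from Cardan angles
#'
#' `R = R1(a1) %*% R2(a2) %*% R3(a3)` for the given axis sequence, e.g.
#' `"yxz"`. Used as the round-trip oracle for [cardan_angles()].
#'
#' @param angles_deg length-3 numeric, degrees.
#' @param sequence three-letter axis string from {x, y, z}, all distinct.
#' @return 3x3 rotation matrix.
#' @export
cardan_compose <- function(angles_deg, sequence = "yxz") {
  ax <- strsplit(sequence, "")[[1]]
  stopifnot(length(ax) == 3, all(ax %in% c("x", "y", "z")))
  a <- angles_deg * pi / 180
  axis_rot(ax[1], a[1]) %*% axis_rot(ax[2], a[2]) %*% axis_rot(ax[3], a[3])
}

#' Cardan angle decomposition
#'
#' Decomposes the rotation of a distal frame relative to a proximal frame,
#' `R = t(Rp) %*% Rd`, into three ordered rotations about body-fixed axes.
#' Supports all six tri-axis Cardan sequences. Flags gimbal proximity when
#' the middle angle is within 1 degree of +/-90.
#'
#' @param proximal 3x3 rotation matrix (columns = frame axes in lab).
#' @param distal 3x3 rotation matrix.
#' @param sequence axis order, e.g. `"yxz"` (flexion about y first).
#' @return numeric length-3 (degrees), attribute `gimbal` logical.
#' @export
cardan_angles <- function(proximal, distal, sequence = "yxz") {
  for (R in list(proximal, distal)) {
    if (max(abs(crossprod(R) - diag(3))) > 1e-6 || det(R) < 0)
      stop("frames must be right-handed orthonormal rotation matrices")
  }
  R <- t(proximal) %*% distal
  ax <- strsplit(sequence, "")[[1]]
  i <- match(ax[1], c("x", "y", "z"))
  j <- match(ax[2], c("x", "y", "z"))
  k <- match(ax[3], c("x", "y", "z"))
  # cyclic (e.g. xyz) vs anti-cyclic (e.g. xzy) sequences differ in sign
  cyclic <- (j - i) %% 3 == 1
  s <- if (cyclic) 1 else -1
  a2 <- asin(pmin(1, pmax(-1, s * R[i, k])))
  a1 <- atan2(-s * R[j, k], R[k, k])
  a3 <- atan2(-s * R[i, j], R[i, i])
  out <- c(a1, a2, a3) * 180 / pi
  attr(out, "gimbal") <- abs(abs(out[2]) - 90) < 1
  out
}

#' Cardan angle time series for a joint
#'
#' Applies [cardan_angles()] frame-wise and unwraps each angle channel so
#' there are no +/-180 degree jumps.
#'
#' @param proximal_frames list (or 3x3xN array) of proximal rotations.
#' @param distal_frames list (or 3x3xN array) of distal rotations.
#' @param sequence Cardan order for this joint.
#' @return N x 3 matrix of degrees, attribute `gimbal` = any frame flagged.
#' @export
cardan_series <- function(proximal_frames, distal_frames, sequence = "yxz") {
  as_list <- function(f) {
    if (is.array(f) && length(dim(f)) == 3)
      lapply(seq_len(dim(f)[3]), function(i) f[, , i]) else f
  }
  pf <- as_list(proximal_frames); df <- as_list(distal_frames)
  stopifnot(length(pf) == length(df))
  ang <- t(mapply(function(p, d) cardan_angles(p, d, sequence), pf, df))
  gimbal <- any(vapply(seq_along(pf), function(i)
    isTRUE(attr(cardan_angles(pf[[i]], df[[i]], sequence), "gimbal")),
    logical(1)))
  ang <- apply(ang, 2, function(a) {
    rad <- a * pi / 180
    (rad[1] + cumsum(c(0, diff(rad) - 2 * pi * round(diff(rad) / (2 * pi))))) *
      180 / pi
  })
  attr(ang, "gimbal") <- gimbal
  ang
}

#' Range of motion within a phase
#'
#' ROM = max - min of each angle channel over the samples falling inside the
#' phase interval (inclusive).
#'
#' @param angles N x 3 matrix of degrees (see [cardan_series()]).
#' @param times sample times (seconds).
#' @param phase length-2 numeric `c(t_start, t_end)`.
#' @return length-3 numeric, degrees.
#' @export
range_of_motion <- function(angles, times, phase) {
  idx <- which(times >= phase[1] - 1e-9 & times <= phase[2] + 1e-9)
  if (length(idx) == 0) stop("phase contains no samples")
  apply(angles[idx, , drop = FALSE], 2, function(a) max(a) - min(a))
}

# ---- segment coordinate systems -------------------------------------------

normalize_rows <- function(m) m / sqrt(rowSums(m^2))
cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# Build per-frame rotation matrices from a longitudinal axis (k, pointing
# proximal) and a medio-lateral reference axis. Columns: x anterior,
# y to the left, z proximal (right-handed).
frames_from_axes <- function(long_axis, ml_axis) {
  z <- normalize_rows(long_axis)
  x <- normalize_rows(cross3(ml_axis, z))    # anterior = ml x up
  y <- cross3(z, x)
  n <- nrow(z)
  lapply(seq_len(n), function(i)
    cbind(x[i, ], y[i, ], z[i, ]))
}

#' Segment coordinate systems for the lower limbs and pelvis
#'
#' Builds right-handed orthonormal frames per frame: pelvis from the ASIS
#' pair and mid-hip->C7 axis; thigh from hip->knee with the epicondyle pair
#' as medio-lateral reference; shank from knee->ankle with the malleolar
#' pair; foot from heel->toe (longitudinal, horizontalish) with the
#' malleolar pair. Conventions: x anterior, y left, z proximal/up.
#'
#' @param markers named list of n x 3 marker trajectories.
#' @return nested list `frames[[segment]][[frame_index]]` of 3x3 matrices.
#' @export
segment_frames <- function(markers) {
  jc <- joint_centres(markers)
  ml <- function(lat, med, side) {
    # medio-lateral axis pointing left (+y): for the left side the lateral
    # marker is on the +y side, for the right side on the -y side
    d <- markers[[lat]] - markers[[med]]
    if (side == "R") -d else d
  }
  out <- list(
    pelvis = frames_from_axes(jc$c7 - jc$mid_hip,
                              markers$ASIS_L - markers$ASIS_R),
    thigh_L = frames_from_axes(jc$hip_L - jc$knee_L, ml("LEPI_L", "MEPI_L", "L")),
    thigh_R = frames_from_axes(jc$hip_R - jc$knee_R, ml("LEPI_R", "MEPI_R", "R")),
    shank_L = frames_from_axes(jc$knee_L - jc$ankle_L, ml("LMAL_L", "MMAL_L", "L")),
    shank_R = frames_from_axes(jc$knee_R - jc$ankle_R, ml("LMAL_R", "MMAL_R", "R")),
    foot_L = foot_frames(markers$HEEL_L, markers$TOE_L, ml("LMAL_L", "MMAL_L", "L")),
    foot_R = foot_frames(markers$HEEL_R, markers$TOE_R, ml("LMAL_R", "MMAL_R", "R"))
  )
  out
}

# Foot SCS: x along heel->toe (anterior), z dorsal (up for a flat foot),
# y left; so a flat foot under a vertical shank gives a near-identity
# ankle rotation.
foot_frames <- function(heel, toe, ml_axis) {
  x <- normalize_rows(toe - heel)
  z <- normalize_rows(cross3(x, ml_axis))   # anterior x left = dorsal
  y <- cross3(z, x)
  lapply(seq_len(nrow(x)), function(i) cbind(x[i, ], y[i, ], z[i, ]))
}

#' Lower-limb joint angle series
#'
#' Computes hip (pelvis-thigh), knee (thigh-shank) and ankle (shank-foot)
#' Cardan angle series per side, all with the `"yxz"` sequence: first
#' rotation about the medio-lateral axis (flexion/extension or
#' plantar/dorsiflexion), second about the anterior axis (ab/adduction,
#' valgus/varus or eversion/inversion), third about the longitudinal axis
#' (axial rotation or ankle ab/adduction).
#'
#' @param markers named list of marker trajectories.
#' @param rate_hz marker sampling rate.
#' @return named list of N x 3 matrices (degrees):
#'   `hip_L, hip_R, knee_L, knee_R, ankle_L, ankle_R`, plus `times`.
#' @export
joint_angle_series <- function(markers, rate_hz) {
  fr <- segment_frames(markers)
  n <- length(fr$pelvis)
  res <- list(
    hip_L = cardan_series(fr$pelvis, fr$thigh_L, "yxz"),
    hip_R = cardan_series(fr$pelvis, fr$thigh_R, "yxz"),
    knee_L = cardan_series(fr$thigh_L, fr$shank_L, "yxz"),
    knee_R = cardan_series(fr$thigh_R, fr$shank_R, "yxz"),
    ankle_L = cardan_series(fr$shank_L, fr$foot_L, "yxz"),
    ankle_R = cardan_series(fr$shank_R, fr$foot_R, "yxz")
  )
  # sign convention: flexion negative at hip and knee, dorsiflexion positive
  for (nm in c("knee_L", "knee_R", "ankle_L", "ankle_R"))
    res[[nm]][, 1] <- -res[[nm]][, 1]
  res$times <- (seq_len(n) - 1) / rate_hz
  res
}

#' Average joint angles across sides
#'
#' Bilateral mean with the right side's frontal and transverse channels
#' mirrored (sign-flipped), so that symmetric abduction/valgus/axial
#' rotation does not cancel.
#'
#' @param left,right N x 3 angle matrices from [joint_angle_series()].
#' @return N x 3 matrix.
#' @export
bilateral_mean <- function(left, right) {
  (left + sweep(right, 2, c(1, -1, -1), "*")) / 2
}
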