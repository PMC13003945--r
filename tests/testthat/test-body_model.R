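test_that("segment parameter table is a closed mass budget", {
  tab <- segment_parameter_table()
  expect_equal(nrow(tab), 15)
  expect_equal(sum(tab$mass_fraction), 1, tolerance = 1e-6)
  expect_true(all(tab$com_ratio > 0 & tab$com_ratio < 1))
  expect_true(all(tab$gyration_ratio > 0 & tab$gyration_ratio < 1))
  model <- reduced_segment_model()
  expect_equal(sum(vapply(model, `[[`, 1, "mass_fraction")), 1,
               tolerance = 1e-9)
})

test_that("whole-body COM is the mass-weighted segment mean", {
  # all joint centres coincident -> COM at that point
  p <- c(0.3, -0.1, 1.21)
  wb <- whole_body_com(toy_markers(p))
  expect_equal(wb$com[1, ], p, tolerance = 1e-9)

  # two-segment toy: fractions 0.6/0.4 at heights 1.0/0.5 -> COM z = 0.8
  mk <- toy_markers(c(0, 0, 1.0))
  mk$C7 <- matrix(c(0, 0, 0.5), 1)
  model2 <- list(
    list(name = "a", mass_fraction = 0.6, com_ratio = 0.5,
         gyration_ratio = 0.3, proximal = "heel_L", distal = "toe_L"),
    list(name = "b", mass_fraction = 0.4, com_ratio = 0.5,
         gyration_ratio = 0.3, proximal = "c7", distal = "c7"))
  expect_equal(whole_body_com(mk, model2)$com[1, 3], 0.8, tolerance = 1e-9)

  bad <- toy_markers(); bad$C7[1, 1] <- NA
  expect_error(whole_body_com(bad), "frames")
})

test_that("COM of the noiseless synthetic trial matches the prescribed COM", {
  wb <- whole_body_com(ref_trial$recording$markers)
  expect_lt(max(abs(wb$com[, 3] - ref_trial$truth$com_z)), 0.005)
})

test_that("Cardan decomposition: identity, single axis, round trip", {
  expect_equal(as.numeric(cardan_angles(diag(3), diag(3))), c(0, 0, 0))
  for (sq in c("xyz", "xzy", "yxz", "yzx", "zxy", "zyx")) {
    R <- cardan_compose(c(30, 0, 0), sq)
    expect_equal(as.numeric(cardan_angles(diag(3), R, sq)), c(30, 0, 0),
                 tolerance = 1e-10, label = sq)
  }
  set.seed(10)
  for (i in 1:20) for (sq in c("xyz", "yxz", "zyx", "yzx")) {
    a <- c(runif(1, -170, 170), runif(1, -80, 80), runif(1, -170, 170))
    R <- cardan_compose(a, sq)
    back <- cardan_compose(as.numeric(cardan_angles(diag(3), R, sq)), sq)
    expect_lt(max(abs(back - R)), 1e-10)
  }
})

test_that("Cardan guards: non-orthonormal frames rejected, gimbal flagged", {
  expect_error(cardan_angles(diag(3) * 1.1, diag(3)), "orthonormal")
  near_gimbal <- cardan_compose(c(10, 89.6, -20), "yxz")
  expect_true(attr(cardan_angles(diag(3), near_gimbal, "yxz"), "gimbal"))
})

test_that("segment frames stay orthonormal through a trial", {
  fr <- segment_frames(ref_trial$recording$markers)
  for (seg in c("pelvis", "thigh_L", "shank_R", "foot_L")) {
    errs <- vapply(fr[[seg]][seq(1, length(fr[[seg]]), by = 25)],
                   function(R) max(abs(crossprod(R) - diag(3))), numeric(1))
    expect_lt(max(errs), 1e-8)
  }
})

test_that("range of motion: constant, sinusoid, empty phase", {
  tt <- seq(0, 2, by = 0.004)
  ang <- cbind(rep(5, length(tt)), 12 * sin(2 * pi * tt), 0)
  rom <- range_of_motion(ang, tt, c(0, 1.5))
  expect_equal(rom[1], 0)
  expect_equal(rom[2], 24, tolerance = 24 * 0.005)
  expect_error(range_of_motion(ang, tt, c(5, 6)), "no samples")
})

test_that("ROMs and contact angles recover the generator truth", {
  f <- ref_analysis$features
  tru <- ref_trial$truth
  # the flexion excursions: knee concentric within 1 degree, rest within 1.5
  expect_lt(abs(f[["knee_rom_ef_con"]] - tru$rom_truth$knee[["con"]]), 1)
  for (j in c("hip", "knee", "ankle")) {
    key <- c(hip = "hip_rom_ef_", knee = "knee_rom_ef_",
             ankle = "ankle_rom_pd_")[[j]]
    for (ph in c("ecc", "con"))
      expect_lt(abs(f[[paste0(key, ph)]] - tru$rom_truth[[j]][[ph]]), 1.5)
  }
  # flexed landing posture: hip and knee flexion negative at ground contact
  expect_lt(f[["hip_ef_gc"]], -5)
  expect_lt(f[["knee_ef_gc"]], -5)
  # frontal/transverse excursions are non-degenerate
  expect_gt(f[["knee_rom_vv_con"]], 0.5)
  expect_gt(f[["hip_rom_rot_con"]], 0.5)
  expect_gt(f[["ankle_rom_ei_con"]], 0.5)
})
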