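test_that("jump height and RSI closed forms and guards", {
  expect_equal(jump_height(1.0), 1 / (2 * 9.81))
  expect_error(jump_height(0), "upward")
  expect_error(jump_height(-0.5), "upward")
  expect_equal(reactive_strength_index(0.30, 0.20), 1.5)
  expect_equal(reactive_strength_index(0, 0.2), 0)
  expect_error(reactive_strength_index(0.3, 0), "positive")
})

test_that("phase impulse: rectangle exactly, triangle within discretization", {
  fs <- 1000; mass <- 80
  tt <- seq(0, 0.5, by = 1 / fs)
  rect <- sampled_signal(ifelse(tt >= 0.1 & tt <= 0.2, 10 * mass, 0), fs)
  expect_equal(phase_impulse(rect, c(0.1, 0.2), mass), 1.0, tolerance = 1e-3)

  # triangular pulse peak P over duration d -> P d / 2
  P <- 30; d <- 0.2
  tri <- sampled_signal(pmax(0, P * (1 - abs(tt - 0.25) / (d / 2))) * mass, fs)
  expect_equal(phase_impulse(tri, c(0.15, 0.35), mass), P * d / 2,
               tolerance = P * d / 2 * 1e-3)
  expect_error(phase_impulse(rect, c(0.8, 0.9), mass), "too few")
})

test_that("GRF summaries on constructed signals match closed forms", {
  fs <- 1000; mass <- 70
  tt <- seq(0, 0.5, by = 1 / fs)
  ev <- structure(list(t_contact = 0.10, t_com_min = 0.25, t_takeoff = 0.40),
                  class = "trial_events")
  # force rising linearly to 60 N/kg at t_com_min then back down
  fnorm <- pmax(0, 60 * (1 - abs(tt - 0.25) / 0.15))
  fz <- sampled_signal(fnorm * mass, fs)
  # COM descending 0.15 m to its minimum at t_com_min, then back up
  com <- sampled_signal(1 - 0.15 * pmax(0, 1 - (abs(tt - 0.25) / 0.15)^2), fs)
  gs <- grf_summaries(fz, ev, com, mass)
  expect_equal(gs$peak_grf_ecc, 60, tolerance = 0.01)
  expect_equal(gs$stiffness, 60 / 0.15, tolerance = 0.5)   # 400 N/m/kg
  expect_equal(gs$rfd, 60 / 0.15, tolerance = 1)           # rise time 0.15 s
  expect_equal(gs$synchro, 0, tolerance = 0.3)             # peak at COM min
  expect_equal(gs$f_zero_vel, 60, tolerance = 0.1)
  expect_equal(gs$mean_grf_ecc, 30, tolerance = 0.2)
})

test_that("COM power and work: zero velocity, constant force, length guard", {
  fs <- 1000; mass <- 70
  n <- 101
  fz <- sampled_signal(rep(mass * 9.81, n), fs)
  v0 <- sampled_signal(rep(0, n), fs)
  expect_equal(com_power_work(fz, v0, c(0, 0.1), mass)$work, 0)
  v1 <- sampled_signal(rep(1, n), fs)
  expect_equal(com_power_work(fz, v1, c(0, 0.1), mass)$work, 0.981,
               tolerance = 1e-3)
  expect_error(com_power_work(fz, sampled_signal(rep(1, 50), fs),
                              c(0, 0.05), mass), "timebase")
})

test_that("trial features satisfy their defining identities", {
  f <- ref_analysis$features
  tru <- ref_trial$truth
  expect_equal(f[["rsi"]], f[["ht"]] / f[["ct"]], tolerance = 1e-9)
  expect_equal(f[["imp_ratio"]], f[["imp_ecc"]] / f[["imp_con"]],
               tolerance = 1e-9)
  expect_equal(f[["ct"]], f[["ct_ecc"]] + f[["ct_con"]], tolerance = 1e-9)
  # truth recovery at the documented tolerances
  expect_lt(abs(f[["ht"]] - tru$jump_height_m), 0.005)
  expect_lt(abs(f[["imp_ratio"]] - tru$impulse_ecc / tru$impulse_con), 0.02)
  expect_lt(abs(f[["work_con"]] - tru$com_work_con) / tru$com_work_con, 0.02)
  expect_lt(abs(f[["grf_peak_ecc"]] - tru$peak_fz_n_kg) / tru$peak_fz_n_kg,
            0.02)
})

test_that("feature table assembly: shape, units, aggregation invariance", {
  # three pseudo-trials for two participants from jittered copies of the
  # reference feature vector
  f <- ref_analysis$features
  jitter_fv <- function(s) { set.seed(s); f * (1 + rnorm(length(f), 0, 0.01)) }
  p1 <- list(list(features = jitter_fv(1)), list(features = jitter_fv(2)),
             list(features = jitter_fv(3)))
  tab <- assemble_feature_table(list(p1, list(list(features = f))))
  expect_equal(dim(tab), c(2, 47))
  expect_equal(sum(feature_catalog()$role == "predictor"), 44)
  units <- attr(tab, "units")
  expect_true(all(nzchar(units)))
  expect_equal(unname(units[c("ct", "ht", "rsi", "stiffness")]),
               c("s", "m", "m/s", "N/m/kg"))

  perm <- assemble_feature_table(list(p1[c(3, 1, 2)],
                                      list(list(features = f))))
  expect_equal(tab, perm)

  best <- assemble_feature_table(list(p1), aggregate = "best")
  rsis <- vapply(p1, function(x) x$features[["rsi"]], numeric(1))
  expect_equal(best$rsi[1], max(rsis))

  broken <- list(list(list(features = f[-5])))
  expect_error(assemble_feature_table(broken), "missing variables")
})
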