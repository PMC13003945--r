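test_that("generator rejects non-physical parameter sets", {
  expect_error(generate_trial(anthropometry = list(height_m = 1.7,
                                                   mass_kg = -5)),
               "positive")
  expect_error(generate_trial(dj_profile(drop_height = -0.1)), "positive")
  expect_error(generate_trial(dj_profile(contact_time = 0.03)), "contact_time")
  expect_error(generate_trial(dj_profile(drop_height = 1.2)), "leg length")
})

test_that("truth satisfies its defining identities", {
  tru <- ref_trial$truth
  expect_equal(tru$rsi, tru$jump_height_m / tru$contact_time_s)
  expect_true(tru$t_contact < tru$t_com_min &&
                tru$t_com_min < tru$t_takeoff &&
                tru$t_takeoff < tru$t_landing)
  # GRF is zero in the air
  tf <- signal_times(ref_trial$recording$forces)
  fz <- rowSums(ref_trial$recording$forces$values[, c("fz1", "fz2")])
  air <- tf < tru$t_contact - 2e-3 |
    (tf > tru$t_takeoff + 2e-3 & tf < tru$t_landing - 2e-3)
  expect_equal(max(abs(fz[air])), 0)
})

test_that("prescribed outcomes are recovered by the analysis pipeline", {
  tr <- generate_trial(dj_profile(jump_height = 0.30))
  an <- analyze_trial(tr$recording, compute_joint_work = FALSE)
  expect_lt(abs(an$features[["ht"]] - 0.30), 0.005)

  # threshold detection on the raw constructed force: within 2 samples
  fzsum <- sampled_signal(rowSums(tr$recording$forces$values[, c("fz1", "fz2")]),
                          1000)
  ev <- detect_contact_takeoff(fzsum, 20)
  expect_lt(abs(ev$contact_time - tr$truth$contact_time_s), 2e-3 + 1e-9)
})

test_that("impulse-momentum closure against a trapezoidal oracle", {
  tr <- generate_trial(noise_sd = 0.002, seed = 1)
  m <- tr$truth$body_mass_kg
  tf <- signal_times(tr$recording$forces)
  fz <- rowSums(tr$recording$forces$values[, c("fz1", "fz2")])
  idx <- tf <= tr$truth$t_takeoff
  J <- sum(diff(tf[idx]) * (utils::head(fz[idx], -1) +
                              utils::tail(fz[idx], -1)) / 2) -
    m * g_const * max(tf[idx])
  expect_lt(abs(J - m * tr$truth$v_takeoff), 0.02 * m * tr$truth$v_takeoff)
})

test_that("flight-time height agrees with the velocity definition", {
  ev <- ref_analysis$events
  h_ft <- g_const * ev$flight_time^2 / 8
  expect_lt(abs(h_ft - ref_analysis$features[["ht"]]) /
              ref_analysis$features[["ht"]], 0.02)
})

test_that("generation is bit-reproducible under a fixed seed", {
  a <- generate_trial(noise_sd = 0.003, seed = 42)
  b <- generate_trial(noise_sd = 0.003, seed = 42)
  expect_identical(a$recording$markers, b$recording$markers)
  expect_identical(a$recording$forces$values, b$recording$forces$values)
  c_ <- generate_trial(noise_sd = 0.003, seed = 43)
  expect_false(identical(a$recording$markers, c_$recording$markers))
})

test_that("tabular generator: shapes, determinism, guards, noiseless fit", {
  tt <- latent_truth(seed = 5)
  d <- generate_pls_dataset(tt)
  expect_equal(dim(d$X), c(43, 44))
  expect_gte(qr(d$X)$rank, tt$n_latent)
  d2 <- generate_pls_dataset(tt)
  expect_identical(d$X, d2$X); expect_identical(d$y, d2$y)
  expect_equal(population_r2(tt), 0.9, tolerance = 1e-12)

  expect_error(latent_truth(n_samples = 4, n_latent = 3), "n_samples")
  expect_error(latent_truth(loading_matrix = matrix(1, 3, 2), n_latent = 3),
               "dimensions")

  # duplicated predictor on an otherwise well-conditioned table: the
  # correlation filter removes exactly one of the pair
  set.seed(30)
  Z <- matrix(rnorm(43 * 10), 43)
  colnames(Z) <- paste0("x", 1:10)
  X <- cbind(Z, dup = Z[, 1])
  rep <- correlation_filter(scale(X))
  expect_equal(nrow(rep$removed), 1)
  expect_true(rep$removed$name %in% c("x1", "dup"))
})
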