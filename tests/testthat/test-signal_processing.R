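test_that("zero-lag Butterworth has unit DC gain and validates its cutoff", {
  fs <- 1000
  x <- sampled_signal(rep(3.7, 500), fs)
  y <- butterworth_zero_lag(x, 20)
  expect_equal(y$values[, 1], rep(3.7, 500), tolerance = 1e-9)
  expect_error(butterworth_zero_lag(x, 500), "Nyquist")
  expect_error(butterworth_zero_lag(x, 0), "Nyquist")
})

test_that("dual-pass amplitude at the design frequency is 0.5, low band preserved", {
  fs <- 1000; fc <- 20
  tt <- seq(0, 4, by = 1 / fs)
  mid <- seq(round(length(tt) * 0.25), round(length(tt) * 0.75))
  amp_ratio <- function(f_sig) {
    x <- sin(2 * pi * f_sig * tt)
    y <- butterworth_zero_lag(sampled_signal(x, fs), fc)$values[, 1]
    max(abs(y[mid])) / max(abs(x[mid]))
  }
  # single-pass |H|^2 = 1/2 at fc, so the dual pass halves the amplitude
  expect_equal(amp_ratio(fc), 0.5, tolerance = 0.01)
  expect_equal(amp_ratio(0.01 * fc), 1, tolerance = 1e-3)
})

test_that("zero-lag property: cross-correlation peak at lag 0", {
  fs <- 500
  tt <- seq(0, 3, by = 1 / fs)
  x <- sin(2 * pi * 3 * tt) + 0.5 * sin(2 * pi * 7 * tt)
  y <- butterworth_zero_lag(sampled_signal(x, fs), 15)$values[, 1]
  cc <- stats::ccf(y, x, lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("filtering commutes with trimming away from the edges", {
  fs <- 250
  tt <- seq(0, 2, by = 1 / fs)
  x <- sin(2 * pi * 2 * tt) + 0.2 * cos(2 * pi * 9 * tt)
  full <- butterworth_zero_lag(sampled_signal(x, fs), 12)$values[, 1]
  sub <- 101:400
  trimmed <- butterworth_zero_lag(sampled_signal(x[sub], fs), 12)$values[, 1]
  core <- 80:220  # interior of the trimmed window
  expect_lt(max(abs(full[sub][core] - trimmed[core])), 1e-6)
})

test_that("residual analysis selects sensible cutoffs", {
  fs <- 250
  tt <- seq(0, 4, by = 1 / fs)
  set.seed(5)
  cands <- seq(2, 30, by = 1)

  noise_only <- sampled_signal(rnorm(length(tt)), fs)
  sel0 <- suppressWarnings(residual_analysis_cutoff(noise_only, cands))
  expect_equal(as.numeric(sel0), min(cands))

  sig <- sampled_signal(sin(2 * pi * 3 * tt) + rnorm(length(tt), 0, 0.05), fs)
  sel <- residual_analysis_cutoff(sig, cands)
  expect_gte(as.numeric(sel), 3)
  expect_lte(as.numeric(sel), 12)

  # noiseless band-limited input: the fourth-order roll-off is shallow, so
  # the residual decays gradually above the 3 Hz band and the intercept
  # criterion lands between the band edge and the conventional 20 Hz
  clean <- sampled_signal(sin(2 * pi * 3 * tt), fs)
  sel2 <- suppressWarnings(residual_analysis_cutoff(clean, cands))
  expect_gt(as.numeric(sel2), 3)
  expect_lt(as.numeric(sel2), 20)
})

test_that("align_and_resample is exact on shared timebases and polynomials", {
  fs <- 250
  x <- sampled_signal(sin(seq(0, 3, by = 1 / fs)), fs)
  out <- align_and_resample(x, x)
  expect_equal(out$markers$values, x$values, tolerance = 1e-12)

  tt <- seq(0, 1, by = 1 / 250)
  ramp <- sampled_signal(2.5 * tt - 1, 250)
  f1k <- sampled_signal(rep(0, 1001), 1000)
  res <- align_and_resample(ramp, f1k)
  tout <- signal_times(res$markers)
  expect_equal(res$markers$values[, 1], 2.5 * tout - 1, tolerance = 1e-9)

  late <- sampled_signal(rep(0, 100), 100, t0 = 50)
  expect_error(align_and_resample(ramp, late), "overlap")
})

test_that("take-off velocity agrees across timebases on a generated trial", {
  rec <- ref_trial$recording
  fs <- rec$marker_rate_hz
  fmk <- lapply(rec$markers, function(x)
    butterworth_zero_lag(sampled_signal(x, fs), 20)$values)
  com250 <- sampled_signal(whole_body_com(fmk)$com[, 3], fs)
  v250 <- central_derivative(com250)
  t_to <- ref_trial$truth$t_takeoff
  v1 <- stats::approx(signal_times(v250), v250$values[, 1], xout = t_to)$y
  fz <- sampled_signal(rowSums(rec$forces$values[, c("fz1", "fz2")]), 1000)
  com1k <- align_and_resample(com250, fz)$markers
  v1k <- central_derivative(com1k)
  v2 <- stats::approx(signal_times(v1k), v1k$values[, 1], xout = t_to)$y
  expect_lt(abs(v1 - v2) / abs(v2), 0.005)
})
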