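#' Sampled signal container
#'
#' A thin container for uniformly sampled multichannel data: a numeric matrix
#' (samples x channels) plus a sampling rate and a start time. All filtering,
#' resampling and event-detection functions in the package accept and return
#' this class.
#'
#' @param values numeric vector or matrix (samples in rows).
#' @param rate_hz sampling rate in Hz (> 0).
#' @param t0 time of the first sample in seconds.
#' @param channels optional channel names.
#' @return an object of class `sampled_signal`.
#' @export
sampled_signal <- function(values, rate_hz, t0 = 0, channels = NULL) {
  if (is.vector(values)) values <- matrix(values, ncol = 1)
  values <- as.matrix(values)
  if (!is.numeric(rate_hz) || length(rate_hz) != 1 || rate_hz <= 0)
    stop("rate_hz must be a single positive number")
  if (any(!is.finite(values)))
    stop("sampled_signal values must be finite")
  if (!is.null(channels)) colnames(values) <- channels
  structure(list(values = values, rate_hz = rate_hz, t0 = t0),
            class = "sampled_signal")
}

#' @export
print.sampled_signal <- function(x, ...) {
  cat(sprintf("<sampled_signal: %d samples x %d channels @ %g Hz, t0 = %g s>\n",
              nrow(x$values), ncol(x$values), x$rate_hz, x$t0))
  invisible(x)
}

#' Time vector of a sampled signal
#' @param x a `sampled_signal`.
#' @return numeric vector of sample times in seconds.
#' @export
signal_times <- function(x) {
  stopifnot(inherits(x, "sampled_signal"))
  x$t0 + (seq_len(nrow(x$values)) - 1) / x$rate_hz
}

# Second-order low-pass Butterworth coefficients via the bilinear transform.
# Returns list(b = c(b0,b1,b2), a = c(1,a1,a2)).
butter2_lowpass_coef <- function(cutoff_hz, rate_hz) {
  K <- tan(pi * cutoff_hz / rate_hz)
  den <- 1 + sqrt(2) * K + K^2
  b <- c(K^2, 2 * K^2, K^2) / den
  a <- c(1, 2 * (K^2 - 1) / den, (1 - sqrt(2) * K + K^2) / den)
  list(b = b, a = a)
}

# One-directional IIR biquad with steady-state (DC) initial conditions.
iir_biquad <- function(x, b, a) {
  n <- length(x)
  y <- numeric(n)
  # assume the signal was at x[1] forever before the record starts
  xm1 <- x[1]; xm2 <- x[1]; ym1 <- x[1]; ym2 <- x[1]
  for (i in seq_len(n)) {
    y[i] <- b[1] * x[i] + b[2] * xm1 + b[3] * xm2 - a[2] * ym1 - a[3] * ym2
    xm2 <- xm1; xm1 <- x[i]
    ym2 <- ym1; ym1 <- y[i]
  }
  y
}

# Odd (point-reflected) padding about both endpoints.
reflect_pad <- function(x, np) {
  n <- length(x)
  np <- min(np, n - 1)
  head_pad <- 2 * x[1] - x[(np + 1):2]
  tail_pad <- 2 * x[n] - x[(n - 1):(n - np)]
  list(x = c(head_pad, x, tail_pad), np = np)
}

#' Fourth-order zero-lag Butterworth low-pass filter
#'
#' Dual-pass (forward then backward) second-order Butterworth low-pass,
#' giving a fourth-order zero-phase response. Edge effects are controlled by
#' odd-reflection padding of roughly one settling length. By default the
#' requested cutoff is used directly for each pass (so the dual-pass -3 dB
#' point sits slightly below the nominal cutoff); set `correct_cutoff = TRUE`
#' to pre-warp the per-pass cutoff by the standard dual-pass correction
#' factor 0.802 so that the combined response is -3 dB at `cutoff_hz`.
#'
#' @param signal a `sampled_signal`.
#' @param cutoff_hz low-pass cutoff in Hz, must lie in (0, Nyquist).
#' @param correct_cutoff apply the dual-pass cutoff correction factor.
#' @return a `sampled_signal` of the same shape.
#' @export
butterworth_zero_lag <- function(signal, cutoff_hz, correct_cutoff = FALSE) {
  stopifnot(inherits(signal, "sampled_signal"))
  fs <- signal$rate_hz
  if (cutoff_hz <= 0 || cutoff_hz >= fs / 2)
    stop("cutoff_hz must lie strictly between 0 and the Nyquist frequency")
  n <- nrow(signal$values)
  if (n < 9) stop("signal too short to filter (need >= 3x filter order)")
  fc <- if (correct_cutoff) cutoff_hz / 0.802 else cutoff_hz
  if (fc >= fs / 2) fc <- 0.999 * fs / 2
  co <- butter2_lowpass_coef(fc, fs)
  np <- max(9L, ceiling(3 * fs / fc))
  out <- apply(signal$values, 2, function(x) {
    p <- reflect_pad(x, np)
    y <- iir_biquad(p$x, co$b, co$a)
    y <- rev(iir_biquad(rev(y), co$b, co$a))
    y[(p$np + 1):(p$np + n)]
  })
  sampled_signal(out, fs, signal$t0, channels = colnames(signal$values))
}

#' Residual-analysis cutoff selection
#'
#' Winter-style residual analysis: for each candidate cutoff the RMS residual
#' between the raw and the zero-lag-filtered signal is computed; a straight
#' line is fitted to the high-frequency (noise-dominated) tail of the
#' residual curve, and the selected cutoff is the lowest candidate whose
#' residual does not exceed the zero-frequency intercept of that line.
#'
#' The noise region is taken as the upper third of the candidate range. If no
#' candidate meets the intercept criterion (e.g. the input is pure noise so
#' the residual curve is linear everywhere), the minimum candidate is
#' returned with a warning.
#'
#' @param signal a single-channel `sampled_signal`.
#' @param candidate_cutoffs_hz increasing vector of candidate cutoffs (Hz),
#'   spanning at least 2-30 Hz for gait-type data.
#' @return selected cutoff (Hz) with attributes `residuals` and `intercept`.
#' @export
residual_analysis_cutoff <- function(signal,
                                     candidate_cutoffs_hz = seq(2, 30, by = 1)) {
  stopifnot(inherits(signal, "sampled_signal"))
  fcs <- sort(unique(candidate_cutoffs_hz))
  if (length(fcs) < 4) stop("need at least 4 candidate cutoffs")
  x <- signal$values[, 1]
  n <- length(x)
  trim <- max(1L, round(0.05 * n))          # exclude filter edge region
  idx <- (trim + 1):(n - trim)
  res <- vapply(fcs, function(fc) {
    y <- butterworth_zero_lag(signal, fc)$values[, 1]
    sqrt(mean((x[idx] - y[idx])^2))
  }, numeric(1))
  hi <- fcs >= fcs[1] + 2 / 3 * (fcs[length(fcs)] - fcs[1])
  if (sum(hi) < 2) hi[length(hi) - 1:0] <- TRUE
  fit <- stats::lm.fit(cbind(1, fcs[hi]), res[hi])
  a0 <- fit$coefficients[1]
  ok <- which(res <= a0)
  if (length(ok) == 0) {
    warning("residual curve never meets the noise-line intercept; ",
            "returning the minimum candidate cutoff")
    sel <- fcs[1]
  } else {
    sel <- fcs[min(ok)]
  }
  attr(sel, "residuals") <- data.frame(cutoff_hz = fcs, rms_residual = res)
  attr(sel, "intercept") <- unname(a0)
  sel
}

#' Align marker and force series on a common timebase
#'
#' Interpolates the (slower) kinematic series onto the force-plate timebase
#' with cubic splines so that event-referenced quantities can be read at
#' force-plate resolution. The interpolation reproduces the original samples
#' exactly at their own instants.
#'
#' @param markers a `sampled_signal` (e.g. 250 Hz).
#' @param forces a `sampled_signal` (e.g. 1000 Hz).
#' @return list with `markers` resampled to the force timebase (restricted to
#'   the overlapping range) and `forces` trimmed to the same range.
#' @export
align_and_resample <- function(markers, forces) {
  stopifnot(inherits(markers, "sampled_signal"), inherits(forces, "sampled_signal"))
  tm <- signal_times(markers); tf <- signal_times(forces)
  lo <- max(tm[1], tf[1]); hi <- min(tm[length(tm)], tf[length(tf)])
  if (lo >= hi) stop("marker and force time ranges do not overlap")
  keep <- tf >= lo - 1e-12 & tf <= hi + 1e-12
  tout <- tf[keep]
  vals <- apply(markers$values, 2, function(x)
    stats::spline(tm, x, xout = tout, method = "fmm")$y)
  list(
    markers = sampled_signal(vals, forces$rate_hz, tout[1],
                             channels = colnames(markers$values)),
    forces = sampled_signal(forces$values[keep, , drop = FALSE],
                            forces$rate_hz, tout[1],
                            channels = colnames(forces$values))
  )
}

#' Central-difference derivative of a sampled signal
#'
#' First or second time derivative by central differences (one-sided at the
#' record ends).
#'
#' @param x a `sampled_signal` or numeric vector.
#' @param rate_hz sampling rate, required when `x` is a bare vector.
#' @param order 1 (velocity) or 2 (acceleration).
#' @return same type as `x`.
#' @export
central_derivative <- function(x, rate_hz = NULL, order = 1) {
  if (inherits(x, "sampled_signal")) {
    v <- apply(x$values, 2, central_derivative, rate_hz = x$rate_hz, order = order)
    return(sampled_signal(v, x$rate_hz, x$t0, channels = colnames(x$values)))
  }
  dt <- 1 / rate_hz
  n <- length(x)
  if (order == 1) {
    d <- numeric(n)
    d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
    d[1] <- (x[2] - x[1]) / dt
    d[n] <- (x[n] - x[n - 1]) / dt
    d
  } else if (order == 2) {
    d <- numeric(n)
    d[2:(n - 1)] <- (x[3:n] - 2 * x[2:(n - 1)] + x[1:(n - 2)]) / dt^2
    d[1] <- d[2]; d[n] <- d[n - 1]
    d
  } else stop("order must be 1 or 2")
}
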