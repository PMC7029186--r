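# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the peak oracle evaluates the parabola on a
# dense grid, the band-power oracle is a direct periodogram sum, and the
# quadratic-fit oracle minimizes the SSE with Nelder-Mead.

# Brute-force peak call: grid-evaluate a0 + a1*tau + a2*tau^2 on [25, 50] ms
# and ask whether the maximum is attained strictly inside the interval.
oracle_peak <- function(a0, a1, a2, step = 0.001) {
  tau <- seq(25, 50, by = step)
  y <- a0 + a1 * tau + a2 * tau^2
  i <- which.max(y)
  i > 1 && i < length(tau)
}

# Direct periodogram band power of a raw sample vector.
oracle_band_power <- function(x, rate_hz, f1, f2) {
  n <- length(x)
  sp <- Mod(stats::fft(x - mean(x)))^2 / n
  f <- (0:(n - 1)) / n * rate_hz
  sum(sp[f >= f1 & f <= f2])
}

# Dominant frequency of a segment by periodogram argmax above f_min.
oracle_dominant_freq <- function(x, rate_hz, f_min = 5, f_max = 100) {
  n <- length(x)
  sp <- Mod(stats::fft(x - mean(x)))^2
  f <- (0:(n - 1)) / n * rate_hz
  sel <- f >= f_min & f <= f_max
  f[sel][which.max(sp[sel])]
}

# Independent least-squares quadratic fit by direct SSE minimization.
oracle_quad_fit <- function(tau, y) {
  sse <- function(p) sum((y - p[1] - p[2] * tau - p[3] * tau^2)^2)
  start <- c(mean(y), 0, 0)
  o <- stats::optim(start, sse, method = "Nelder-Mead",
                    control = list(maxit = 20000, reltol = 1e-14))
  o <- stats::optim(o$par, sse, method = "Nelder-Mead",
                    control = list(maxit = 20000, reltol = 1e-14))
  o$par
}

# Oracle epoch-level detector run end to end with package-independent
# pieces where possible: package acf (shared container) but grid-max call.
oracle_detect_epoch <- function(samples, rate_hz) {
  a <- stats::acf(samples, lag.max = round(0.1 * rate_hz), plot = FALSE,
                  demean = TRUE)$acf[, 1, 1]
  lags_ms <- (0:round(0.1 * rate_hz)) / rate_hz * 1000
  sel <- lags_ms >= 20 & lags_ms <= 50
  co <- oracle_quad_fit(lags_ms[sel], a[sel])
  oracle_peak(co[1], co[2], co[3])
}

make_sine_trace <- function(f, duration_s = 2, rate_hz = 1e4, amp = 1) {
  t <- (0:(duration_s * rate_hz - 1)) / rate_hz
  ts_trace(amp * sin(2 * pi * f * t), rate_hz)
}
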