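#' Parameters of the coupled-oscillator model
#'
#' Two abstract coupled oscillators represent the developing spinal rhythm
#' generator: a harmonic pacemaker kernel whose output is the closed-form
#' drive `F0 * sin(omega0 * (t - t1))`, and a damped oscillator (the
#' half-center network) integrated as
#' `x'' + 2*zeta*omega0*x' + omega0^2*x = F0*sin(omega0*(t - t1)) + F1(t)`,
#' with `omega0 = 2*pi*omega0_hz` rad/s. Both drive terms are gated by the
#' descending "go signal": a step `F1` on `[t1_s, t2_s]`, zero elsewhere.
#' The damping `zeta` models reciprocal glycinergic inhibition (high
#' `zeta` ~ strychnine), the coupling `F0` the influence of the pacemaker
#' (high `F0` ~ 3 dpf, low `F0` ~ 4-5 dpf).
#'
#' @param omega0_hz natural frequency in Hz (default 20; ordinary frequency,
#'   converted to rad/s internally).
#' @param zeta damping coefficient (>= 0; study regimes 0.1 and 0.5).
#' @param F0 coupling coefficient (study regimes 0.5 and 0.01).
#' @param F1 go-signal amplitude (default 1, arbitrary units).
#' @param t1_s,t2_s go-signal gate interval in seconds (default 0.5-2.5).
#' @param dt_s fixed integration step (default 1e-4 s); must satisfy
#'   `dt_s <= 1/(100*omega0_hz)`.
#' @param duration_s simulated duration (default 3 s).
#' @param x0,v0 initial state (default 0, 0).
#' @return validated `oscillator_params` list.
#' @export
oscillator_params <- function(omega0_hz = 20, zeta = 0.1, F0 = 0.5, F1 = 1,
                              t1_s = 0.5, t2_s = 2.5, dt_s = 1e-4,
                              duration_s = 3, x0 = 0, v0 = 0) {
  if (omega0_hz <= 0) stop("`omega0_hz` must be > 0")
  if (zeta < 0) stop("`zeta` must be >= 0")
  if (!(t1_s < t2_s && t2_s <= duration_s))
    stop("need t1_s < t2_s <= duration_s")
  if (dt_s > 1 / (100 * omega0_hz))
    stop(sprintf("dt_s = %g is too large for stable integration; need <= %g",
                 dt_s, 1 / (100 * omega0_hz)))
  structure(list(omega0_hz = omega0_hz, zeta = zeta, F0 = F0, F1 = F1,
                 t1_s = t1_s, t2_s = t2_s, dt_s = dt_s,
                 duration_s = duration_s, x0 = x0, v0 = v0),
            class = "oscillator_params")
}

#' Drive terms of the model at time t
#'
#' Both the pacemaker drive and the go signal are zero outside the gate
#' `[t1_s, t2_s]`; inside, the periodic term is
#' `F0 * sin(2*pi*omega0_hz*(t - t1_s))` and the go term is the constant
#' `F1`.
#'
#' @param t time (scalar or vector), seconds.
#' @param params an [oscillator_params()].
#' @return list with numeric `periodic` and `go`, same length as `t`.
#' @export
drive_signal <- function(t, params) {
  gate <- as.numeric(t >= params$t1_s & t <= params$t2_s)
  list(periodic = params$F0 *
         sin(2 * pi * params$omega0_hz * (t - params$t1_s)) * gate,
       go = params$F1 * gate)
}

#' Integrate the damped oscillator
#'
#' Fixed-step classical 4th-order Runge-Kutta integration of the model ODE
#' from `(x0, v0)`. The drive is evaluated analytically at the substep
#' times; the gate edges coincide with step boundaries at the default
#' parameters, keeping the step discontinuity from degrading convergence.
#'
#' @param params an [oscillator_params()].
#' @return object of class `oscillator_output`: list with `t_s`, `x`, `v`,
#'   `params`.
#' @export
simulate_oscillator <- function(params) {
  stopifnot(inherits(params, "oscillator_params"))
  w <- 2 * pi * params$omega0_hz
  z <- params$zeta
  dt <- params$dt_s
  n <- round(params$duration_s / dt)
  t_s <- (0:n) * dt
  deriv <- function(t, x, v) {
    d <- drive_signal(t, params)
    c(v, d$periodic + d$go - 2 * z * w * v - w^2 * x)
  }
  x <- numeric(n + 1); v <- numeric(n + 1)
  x[1] <- params$x0; v[1] <- params$v0
  for (i in seq_len(n)) {
    t0 <- t_s[i]; xi <- x[i]; vi <- v[i]
    k1 <- deriv(t0, xi, vi)
    k2 <- deriv(t0 + dt / 2, xi + dt / 2 * k1[1], vi + dt / 2 * k1[2])
    k3 <- deriv(t0 + dt / 2, xi + dt / 2 * k2[1], vi + dt / 2 * k2[2])
    k4 <- deriv(t0 + dt, xi + dt * k3[1], vi + dt * k3[2])
    x[i + 1] <- xi + dt / 6 * (k1[1] + 2 * k2[1] + 2 * k3[1] + k4[1])
    v[i + 1] <- vi + dt / 6 * (k1[2] + 2 * k2[2] + 2 * k3[2] + k4[2])
  }
  structure(list(t_s = t_s, x = x, v = v, params = params),
            class = "oscillator_output")
}

#' @export
print.oscillator_output <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "<oscillator_output> F0=%g zeta=%g omega0=%g Hz, %g s @ dt=%g s\n",
    p$F0, p$zeta, p$omega0_hz, p$duration_s, p$dt_s))
  invisible(x)
}

#' Simulate the four published parameter regimes
#'
#' Strong/weak coupling (`F0` 0.5 / 0.01) crossed with weak/strong
#' reciprocal inhibition (`zeta` 0.1 / 0.5), identical gate and duration.
#'
#' @param ... overrides passed to [oscillator_params()] (everything except
#'   `F0` and `zeta`).
#' @return named list of four `oscillator_output`s:
#'   `"F0=0.5,zeta=0.1"`, `"F0=0.5,zeta=0.5"`, `"F0=0.01,zeta=0.1"`,
#'   `"F0=0.01,zeta=0.5"`.
#' @export
regime_outputs <- function(...) {
  regs <- list(c(0.5, 0.1), c(0.5, 0.5), c(0.01, 0.1), c(0.01, 0.5))
  out <- lapply(regs, function(r)
    simulate_oscillator(oscillator_params(F0 = r[1], zeta = r[2], ...)))
  names(out) <- vapply(regs, function(r)
    sprintf("F0=%g,zeta=%g", r[1], r[2]), "")
  out
}

#' Autocorrelation readout of the model output
#'
#' Applies the recording analysis to the model: takes the gated portion of
#' the output, optionally adds seeded Gaussian observation noise, cuts it
#' into consecutive 200-ms windows, and runs the Peak_20-40 pipeline
#' (autocorrelation, quadratic fit, peak conditions) on each window. The
#' rhythm is called detected when at least half the windows pass.
#'
#' @param output an `oscillator_output` from [simulate_oscillator()].
#' @param window_ms analysis window length in ms (default 200).
#' @param noise_sd SD of additive observation noise (default 0).
#' @param seed seed for the noise.
#' @return list with `acf` (mean `acf_fun` across windows), `detected`
#'   (logical), `window_detected` (logical per window), `score`.
#' @export
model_autocorr_analysis <- function(output, window_ms = 200, noise_sd = 0,
                                    seed = NULL) {
  stopifnot(inherits(output, "oscillator_output"))
  p <- output$params
  if (p$t2_s - p$t1_s < window_ms / 1000)
    stop("the go-signal gate is shorter than one analysis window")
  rate <- 1 / p$dt_s
  sel <- output$t_s >= p$t1_s & output$t_s <= p$t2_s
  x <- output$x[sel]
  if (noise_sd > 0)
    x <- with_seed(seed, x + stats::rnorm(length(x), 0, noise_sd))
  nper <- round(window_ms / 1000 * rate)
  n_w <- floor(length(x) / nper)
  acfs <- vector("list", n_w)
  det <- logical(n_w)
  for (k in seq_len(n_w)) {
    seg <- ts_trace(x[((k - 1) * nper + 1):(k * nper)], rate)
    acfs[[k]] <- autocorrelation(seg)
    det[k] <- detect_peak_20_40(fit_autocorr_poly(acfs[[k]]))
  }
  mean_acf <- structure(list(lags_ms = acfs[[1]]$lags_ms,
                             values = Reduce(`+`, lapply(acfs, `[[`, "values")) / n_w),
                        class = "acf_fun")
  list(acf = mean_acf, detected = mean(det) >= 0.5, window_detected = det,
       score = mean(det))
}
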