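#' Specification for a synthetic fictive-swimming recording
#'
#' Describes a ventral-root-like recording in one of four modes:
#' `burst_ctrl` and `burst_str` emulate 3-dpf burst swimming (long, infrequent
#' episodes); `bg_ctrl` and `bg_str` emulate 5-dpf beat-and-glide swimming
#' (short, frequent episodes). `*_ctrl` episodes carry a 20-40 Hz tail-beat
#' component; `*_str` modes emulate glycine blockade: episodes become slow
#' (about 3 Hz) deflections with broadband, non-rhythmic activity, and only a
#' fraction `residual_rhythm_prob` of episodes keep the tail-beat carrier
#' (default 0.4 for `burst_str`, mirroring the persistence of oscillations in
#' a sizeable share of 3-dpf episodes under strychnine, and 0 for `bg_str`).
#'
#' @param mode one of `"burst_ctrl"`, `"burst_str"`, `"bg_ctrl"`, `"bg_str"`.
#' @param tailbeat_hz tail-beat frequency in Hz, must lie in \[20, 40\].
#' @param episode_dur_s mean episode duration in seconds (> 0.2). Defaults:
#'   2 s for burst modes, 0.35 s for beat-and-glide modes.
#' @param episode_rate_hz episode occurrence rate in episodes/s. Defaults:
#'   0.12 for burst modes, 0.8 for beat-and-glide modes.
#' @param snr amplitude ratio of the episode signal to the background noise
#'   SD (the control carrier is scaled like a sinusoid of amplitude
#'   `snr` times the noise SD).
#' @param rate_hz sampling rate, default 10 kHz.
#' @param duration_s recording duration in seconds.
#' @param seed integer seed; identical spec + seed gives bit-identical output.
#' @param carrier `"burst"` (default) models each tail beat as a smooth
#'   compound-discharge wave (Gaussian bump, SD 4 ms, beat times jittered by
#'   2 ms around the regular beat grid); `"sine"` uses a bare sinusoid.
#' @param residual_rhythm_prob probability that a strychnine-mode episode
#'   keeps its tail-beat carrier; `NULL` uses the mode default above.
#' @return a `fictive_spec` list, validated.
#' @export
fictive_spec <- function(mode = c("burst_ctrl", "burst_str", "bg_ctrl", "bg_str"),
                         tailbeat_hz = 30, episode_dur_s = NULL,
                         episode_rate_hz = NULL, snr = 5, rate_hz = 1e4,
                         duration_s = 30, seed = 1,
                         carrier = c("burst", "sine"),
                         residual_rhythm_prob = NULL) {
  mode <- match.arg(mode)
  carrier <- match.arg(carrier)
  burst_like <- startsWith(mode, "burst")
  if (is.null(episode_dur_s)) episode_dur_s <- if (burst_like) 2 else 0.35
  if (is.null(episode_rate_hz)) episode_rate_hz <- if (burst_like) 0.12 else 0.8
  if (is.null(residual_rhythm_prob))
    residual_rhythm_prob <- switch(mode, burst_str = 0.4, bg_str = 0, 1)
  if (!endsWith(mode, "str")) residual_rhythm_prob <- 1
  if (tailbeat_hz < 20 || tailbeat_hz > 40)
    stop("`tailbeat_hz` must lie in [20, 40]")
  if (episode_dur_s <= 0.2)
    stop("`episode_dur_s` must exceed 0.2 s (the episode definition minimum)")
  if (snr <= 0 || rate_hz <= 0 || duration_s <= 0)
    stop("`snr`, `rate_hz` and `duration_s` must be positive")
  structure(list(mode = mode, tailbeat_hz = tailbeat_hz,
                 episode_dur_s = episode_dur_s,
                 episode_rate_hz = episode_rate_hz, snr = snr,
                 rate_hz = rate_hz, duration_s = duration_s,
                 seed = as.integer(seed), carrier = carrier,
                 residual_rhythm_prob = residual_rhythm_prob),
            class = "fictive_spec")
}

# Raised-cosine on/off episode envelope (20 ms ramps) on a sample grid.
episode_envelope <- function(n, rate_hz, ramp_s = 0.02) {
  nr <- min(round(ramp_s * rate_hz), floor(n / 2))
  env <- rep(1, n)
  if (nr > 0) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(nr) / nr))
    env[seq_len(nr)] <- ramp
    env[n + 1 - seq_len(nr)] <- rev(ramp)
  }
  env
}

# One tail-beat carrier segment: unit-RMS-matched to a sinusoid of amplitude 1.
# "burst": one smooth compound-discharge wave per beat (Gaussian bump,
# SD 4 ms), beat times jittered independently (SD 2 ms) around the regular
# grid so the long-run spectral peak stays at `f`.
beat_carrier <- function(n, rate_hz, f, carrier, bump_sd_ms = 4, jitter_ms = 2) {
  t <- (seq_len(n) - 1) / rate_hz
  if (carrier == "sine") return(sin(2 * pi * f * t))
  grid <- seq(-0.05, t[n] + 0.05, by = 1 / f)
  beats <- grid + stats::rnorm(length(grid), 0, jitter_ms / 1000)
  x <- numeric(n)
  s2 <- 2 * (bump_sd_ms / 1000)^2
  for (b in beats) {
    i0 <- max(1L, ceiling((b - 0.02) * rate_hz))
    i1 <- min(n, floor((b + 0.02) * rate_hz))
    if (i0 <= i1) {
      idx <- i0:i1
      x[idx] <- x[idx] + exp(-(t[idx] - b)^2 / s2)
    }
  }
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s == 0) return(x)
  x / s / sqrt(2)  # RMS matched to a unit-amplitude sinusoid
}

# Draw episode intervals (start, end) sequentially until the recording ends.
draw_episodes <- function(spec) {
  min_gap <- if (startsWith(spec$mode, "burst")) 1 else 0.25
  mean_gap <- max(1 / spec$episode_rate_hz - spec$episode_dur_s, min_gap)
  t <- 0
  out <- list()
  repeat {
    gap <- max(min_gap, stats::rexp(1, 1 / mean_gap))
    dur <- stats::rnorm(1, spec$episode_dur_s, 0.2 * spec$episode_dur_s)
    dur <- min(max(dur, max(0.25, 0.5 * spec$episode_dur_s)),
               1.5 * spec$episode_dur_s)
    start <- t + gap
    if (start + dur > spec$duration_s) break
    out[[length(out) + 1L]] <- c(start, start + dur)
    t <- start + dur
  }
  if (length(out) == 0) {
    # an unlucky first gap must not void a recording that can hold an
    # episode; fall back to the minimum gap
    dur <- min(spec$episode_dur_s, spec$duration_s - min_gap)
    if (dur >= max(0.25, 0.5 * spec$episode_dur_s))
      return(matrix(c(min_gap, min_gap + dur), 1))
    stop(sprintf(
      "duration_s = %g is too short to hold one episode (mean episode %g s)",
      spec$duration_s, spec$episode_dur_s))
  }
  do.call(rbind, out)
}

#' Generate a synthetic fictive-swimming trace with ground truth
#'
#' Builds a ventral-root-like recording: unit-SD Gaussian background noise
#' plus amplitude-enveloped episodes (raised-cosine 20 ms ramps). Control
#' episodes carry the tail-beat rhythm at `spec$tailbeat_hz`; strychnine-mode
#' episodes that lose the rhythm instead carry a slow 3 Hz deflection plus
#' broadband within-episode noise.
#'
#' @param spec a [fictive_spec()].
#' @return list with elements `trace` (a [ts_trace()]) and `truth`, a data
#'   frame with one row per episode: `start_s`, `end_s`, `tailbeat_hz`,
#'   `rhythmic`.
#' @examples
#' r <- generate_fictive_trace(fictive_spec("bg_ctrl", duration_s = 10, seed = 7))
#' nrow(r$truth)
#' @export
generate_fictive_trace <- function(spec) {
  stopifnot(inherits(spec, "fictive_spec"))
  with_seed(spec$seed, {
    n <- round(spec$duration_s * spec$rate_hz)
    x <- stats::rnorm(n)
    ep <- draw_episodes(spec)
    rhythmic <- stats::runif(nrow(ep)) < spec$residual_rhythm_prob
    for (k in seq_len(nrow(ep))) {
      i0 <- max(1L, round(ep[k, 1] * spec$rate_hz) + 1L)
      i1 <- min(n, round(ep[k, 2] * spec$rate_hz))
      m <- i1 - i0 + 1L
      env <- episode_envelope(m, spec$rate_hz)
      if (rhythmic[k]) {
        sig <- spec$snr * beat_carrier(m, spec$rate_hz, spec$tailbeat_hz,
                                       spec$carrier)
      } else {
        tt <- (seq_len(m) - 1) / spec$rate_hz
        sig <- spec$snr * sin(2 * pi * 3 * tt) +
          stats::rnorm(m, 0, spec$snr / 2)
      }
      x[i0:i1] <- x[i0:i1] + env * sig
    }
    truth <- data.frame(start_s = ep[, 1], end_s = ep[, 2],
                        tailbeat_hz = ifelse(rhythmic, spec$tailbeat_hz, NA),
                        rhythmic = rhythmic)
    meta <- list(mode = spec$mode, seed = spec$seed, snr = spec$snr,
                 tailbeat_hz = spec$tailbeat_hz)
    list(trace = ts_trace(x, spec$rate_hz, units = "a.u.", meta = meta),
         truth = truth)
  })
}

#' Generate a synthetic IPSC event-train trace
#'
#' Sums a stereotyped postsynaptic-current kernel (difference of
#' exponentials, 1 ms rise, 5 ms decay, unit peak) at event times.
#' Rhythmic trains place events on a periodic grid with Gaussian jitter;
#' arrhythmic trains draw homogeneous Poisson event times.
#'
#' @param rate_hz_events mean event rate in events/s (> 0).
#' @param rhythmic logical; periodic-with-jitter if `TRUE`, Poisson otherwise.
#' @param jitter_sd_ms Gaussian jitter SD in ms for rhythmic trains (>= 0).
#' @param kernel_params list with `rise_ms`, `decay_ms`, `amp`.
#' @param rate_hz sampling rate (default 10 kHz).
#' @param duration_s trace duration in seconds.
#' @param seed integer seed.
#' @return list with `trace` (a [ts_trace()]) and `truth` (list with
#'   `event_times_s`, `rhythmic`).
#' @export
generate_ipsc_trace <- function(rate_hz_events, rhythmic, jitter_sd_ms = 2,
                                kernel_params = list(rise_ms = 1, decay_ms = 5,
                                                     amp = 1),
                                rate_hz = 1e4, duration_s = 10, seed = 1) {
  if (rate_hz_events <= 0) stop("`rate_hz_events` must be > 0")
  if (jitter_sd_ms < 0) stop("`jitter_sd_ms` must be >= 0")
  with_seed(seed, {
    if (rhythmic) {
      times <- seq(0.5 / rate_hz_events, duration_s, by = 1 / rate_hz_events)
      times <- times + stats::rnorm(length(times), 0, jitter_sd_ms / 1000)
    } else {
      times <- cumsum(stats::rexp(ceiling(rate_hz_events * duration_s * 2 + 20),
                                  rate_hz_events))
      times <- times[times < duration_s]
    }
    times <- sort(times[times >= 0 & times < duration_s])
    n <- round(duration_s * rate_hz)
    imp <- numeric(n)
    idx <- pmin(n, floor(times * rate_hz) + 1L)
    for (i in idx) imp[i] <- imp[i] + 1
    tk <- (0:round(0.06 * rate_hz)) / rate_hz
    rise <- kernel_params$rise_ms / 1000
    decay <- kernel_params$decay_ms / 1000
    k <- exp(-tk / decay) - exp(-tk / rise)
    k <- kernel_params$amp * k / max(k)
    x <- stats::convolve(imp, rev(k), type = "open")[seq_len(n)]
    meta <- list(rhythmic = rhythmic, rate_hz_events = rate_hz_events,
                 jitter_sd_ms = jitter_sd_ms, seed = seed)
    list(trace = ts_trace(x, rate_hz, units = "a.u.", meta = meta),
         truth = list(event_times_s = times, rhythmic = rhythmic))
  })
}
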