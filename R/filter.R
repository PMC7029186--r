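#' Zero-phase 1-200 Hz bandpass filter
#'
#' Bandpass-filters a trace with the squared magnitude response of a
#' 4th-order Butterworth bandpass (the response a forward-backward
#' time-domain Butterworth pass would apply), realized in the frequency
#' domain so the phase is exactly zero. Passband gain is ~1, DC and
#' frequencies above `high_hz` are strongly attenuated.
#'
#' @param trace a [ts_trace()].
#' @param low_hz lower band edge in Hz (default 1).
#' @param high_hz upper band edge in Hz (default 200); must be below Nyquist.
#' @param order analog prototype order per edge (default 4).
#' @return the filtered [ts_trace()].
#' @export
bandpass_filter <- function(trace, low_hz = 1, high_hz = 200, order = 4) {
  stopifnot(inherits(trace, "ts_trace"))
  if (low_hz >= high_hz) stop("`low_hz` must be below `high_hz`")
  if (high_hz >= trace$rate_hz / 2)
    stop(sprintf("`high_hz` (%g) must be below the Nyquist frequency (%g)",
                 high_hz, trace$rate_hz / 2))
  x <- trace$samples
  n <- length(x)
  f <- c(0, seq_len(n - 1)) / n * trace$rate_hz
  f <- pmin(f, trace$rate_hz - f)        # two-sided frequency axis
  # |H|^2 of an order-`order` Butterworth bandpass (forward-backward pass)
  hp <- 1 / (1 + (low_hz / pmax(f, .Machine$double.eps))^(2 * order))
  lp <- 1 / (1 + (f / high_hz)^(2 * order))
  gain <- hp * lp
  y <- Re(stats::fft(stats::fft(x) * gain, inverse = TRUE)) / n
  ts_trace(y, trace$rate_hz, units = trace$units,
           meta = c(trace$meta, list(bandpass_hz = c(low_hz, high_hz))))
}
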