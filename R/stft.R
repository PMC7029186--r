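#' Short-time Fourier spectrogram on consecutive 375-ms epochs
#'
#' Splits the trace into consecutive non-overlapping epochs of `epoch_ms`
#' (375 ms, matching the published processing of 30-s recordings), removes
#' each epoch's mean, and returns the FFT magnitude spectrum per epoch up to
#' `max_freq_hz`.
#'
#' @param trace a [ts_trace()], normally bandpass filtered first.
#' @param epoch_ms epoch length in ms (default 375).
#' @param max_freq_hz highest frequency kept (default 200).
#' @return object of class `stft_matrix`: list with `epoch_times_s` (epoch
#'   start times), `freqs_hz`, and `magnitude` (frequencies x epochs).
#' @export
stft_heatmap <- function(trace, epoch_ms = 375, max_freq_hz = 200) {
  stopifnot(inherits(trace, "ts_trace"))
  nper <- round(epoch_ms / 1000 * trace$rate_hz)
  n_ep <- floor(length(trace$samples) / nper)
  if (n_ep < 1)
    stop(sprintf("trace (%.3f s) is shorter than one %g-ms epoch",
                 trace_duration(trace), epoch_ms))
  freqs <- (0:(nper - 1)) / nper * trace$rate_hz
  keep <- freqs <= max_freq_hz
  mag <- vapply(seq_len(n_ep), function(k) {
    seg <- trace$samples[((k - 1) * nper + 1):(k * nper)]
    Mod(stats::fft(seg - mean(seg)))[keep]
  }, numeric(sum(keep)))
  structure(list(epoch_times_s = (seq_len(n_ep) - 1) * nper / trace$rate_hz,
                 freqs_hz = freqs[keep],
                 magnitude = matrix(mag, nrow = sum(keep))),
            class = "stft_matrix")
}

#' @export
print.stft_matrix <- function(x, ...) {
  cat(sprintf("<stft_matrix> %d epochs x %d frequencies (0-%g Hz)\n",
              length(x$epoch_times_s), length(x$freqs_hz), max(x$freqs_hz)))
  invisible(x)
}

#' Plot an STFT spectrogram as a heat map
#'
#' @param x an `stft_matrix` from [stft_heatmap()].
#' @param band_hz optional frequency band to mark with dashed lines
#'   (default `c(20, 40)`, the tail-beat range).
#' @param ... passed to [graphics::image()].
#' @export
plot_stft <- function(x, band_hz = c(20, 40), ...) {
  stopifnot(inherits(x, "stft_matrix"))
  graphics::image(x$epoch_times_s, x$freqs_hz, t(x$magnitude),
                  xlab = "time (s)", ylab = "frequency (Hz)",
                  col = grDevices::hcl.colors(64, "inferno"), ...)
  if (!is.null(band_hz)) graphics::abline(h = band_hz, lty = 2, col = "white")
  invisible(x)
}

#' Write an STFT matrix as CSV (frequencies in rows, epochs in columns)
#' @param x an `stft_matrix`.
#' @param path output CSV path.
#' @export
write_stft_csv <- function(x, path) {
  stopifnot(inherits(x, "stft_matrix"))
  d <- data.frame(freq_hz = x$freqs_hz, x$magnitude)
  names(d)[-1] <- sprintf("t%.3f", x$epoch_times_s)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
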