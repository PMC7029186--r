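#' Normalized autocorrelation of an epoch
#'
#' Biased (taper `1 - k/n`) autocorrelation estimate of a demeaned epoch,
#' normalized so the lag-0 value is 1; lags run from 0 to `max_lag_ms`.
#'
#' @param epoch a [ts_trace()], typically 200 ms long.
#' @param max_lag_ms largest lag in ms (default 100).
#' @return object of class `acf_fun`: list with `lags_ms`, `values`.
#' @export
autocorrelation <- function(epoch, max_lag_ms = 100) {
  stopifnot(inherits(epoch, "ts_trace"))
  if (stats::sd(epoch$samples) == 0)
    stop("zero-variance epoch: autocorrelation undefined")
  lag_max <- round(max_lag_ms / 1000 * epoch$rate_hz)
  lag_max <- min(lag_max, length(epoch$samples) - 1L)
  a <- stats::acf(epoch$samples, lag.max = lag_max, plot = FALSE,
                  demean = TRUE)$acf[, 1, 1]
  structure(list(lags_ms = (0:lag_max) / epoch$rate_hz * 1000,
                 values = as.numeric(a)),
            class = "acf_fun")
}

#' @export
print.acf_fun <- function(x, ...) {
  cat(sprintf("<acf_fun> lags 0-%g ms (%d points)\n",
              max(x$lags_ms), length(x$lags_ms)))
  invisible(x)
}

#' Quadratic fit of the autocorrelation on the 20-50 ms lag window
#'
#' Least-squares fit of `a0 + a1*tau + a2*tau^2` (tau in ms) to the
#' autocorrelation values whose lags fall in `window_ms` (endpoints
#' included). The fitted vertex `-a1/(2*a2)` and the concavity carry the
#' rhythmicity information: a concave-down parabola peaking between 25 and
#' 50 ms indicates a 20-40 Hz rhythm.
#'
#' @param acf an `acf_fun` from [autocorrelation()].
#' @param window_ms fit window in ms, default `c(20, 50)`.
#' @return object of class `acf_poly_fit`: list with `a0`, `a1`, `a2`,
#'   `fit_window_ms`, `vertex_ms` (`NA` when `a2 == 0`), `concave_down`.
#' @export
fit_autocorr_poly <- function(acf, window_ms = c(20, 50)) {
  stopifnot(inherits(acf, "acf_fun"))
  sel <- acf$lags_ms >= window_ms[1] & acf$lags_ms <= window_ms[2]
  if (sum(sel) < 3)
    stop("fewer than 3 autocorrelation lags fall in the fit window")
  tau <- acf$lags_ms[sel]
  y <- acf$values[sel]
  co <- stats::lm.fit(cbind(1, tau, tau^2), y)$coefficients
  a0 <- unname(co[1]); a1 <- unname(co[2]); a2 <- unname(co[3])
  structure(list(a0 = a0, a1 = a1, a2 = a2, fit_window_ms = window_ms,
                 vertex_ms = if (a2 != 0) -a1 / (2 * a2) else NA_real_,
                 concave_down = is.finite(a2) && a2 < 0),
            class = "acf_poly_fit")
}

#' @export
print.acf_poly_fit <- function(x, ...) {
  cat(sprintf(
    "<acf_poly_fit> a0=%.4g a1=%.4g a2=%.4g vertex=%.2f ms concave_down=%s\n",
    x$a0, x$a1, x$a2, x$vertex_ms, x$concave_down))
  invisible(x)
}

#' Peak_20-40 detection rule
#'
#' A peak is detected iff the fitted parabola is concave down (`a2 < 0`)
#' and its vertex lies strictly between 25 and 50 ms -- the lag range of a
#' 20-40 Hz rhythm. Both inequalities are strict; `a2 == 0` never detects.
#'
#' @param fit an `acf_poly_fit` from [fit_autocorr_poly()], or any list with
#'   elements `a1`, `a2`.
#' @return logical scalar.
#' @examples
#' detect_peak_20_40(list(a1 = 70, a2 = -1))   # vertex 35 ms -> TRUE
#' detect_peak_20_40(list(a1 = 120, a2 = -1))  # vertex 60 ms -> FALSE
#' @export
detect_peak_20_40 <- function(fit) {
  a1 <- fit$a1; a2 <- fit$a2
  if (!is.finite(a2) || a2 >= 0) return(FALSE)
  v <- -a1 / (2 * a2)
  is.finite(v) && v > 25 && v < 50
}

#' Per-recording rhythm score
#'
#' Full Peak_20-40 pipeline for one recording: bandpass filter (1-200 Hz,
#' unless `filtered = TRUE`), episode detection (unless `episodes` is
#' supplied), extraction of `n_epochs` 200-ms epochs, autocorrelation,
#' quadratic fit and peak detection per epoch. The score is the exact
#' fraction of epochs with a detected peak.
#'
#' @param trace a [ts_trace()].
#' @param episodes optional data frame of episode intervals; auto-detected
#'   when `NULL`.
#' @param n_epochs number of epochs (default 10).
#' @param epoch_ms epoch length in ms (default 200).
#' @param strategy,seed epoch selection, see [extract_epochs()]; the score
#'   defaults to `"spread"` so the ten epochs sample ten distinct episodes
#'   whenever the recording holds that many.
#' @param filtered set `TRUE` if `trace` is already bandpass filtered.
#' @param ... passed to [detect_episodes()].
#' @return object of class `rhythm_score`: list with `n_epochs`,
#'   `n_detected`, `score`, `fits` (per-epoch `acf_poly_fit`s), `detected`
#'   (logical per epoch), `episodes`.
#' @export
rhythm_score <- function(trace, episodes = NULL, n_epochs = 10,
                         epoch_ms = 200,
                         strategy = c("spread", "earliest", "random"),
                         seed = NULL, filtered = FALSE, ...) {
  strategy <- match.arg(strategy)
  filt <- if (filtered) trace else bandpass_filter(trace)
  if (is.null(episodes)) episodes <- detect_episodes(filt, ...)
  epochs <- extract_epochs(filt, episodes, n = n_epochs, epoch_ms = epoch_ms,
                           strategy = strategy, seed = seed)
  fits <- lapply(epochs, function(e) fit_autocorr_poly(autocorrelation(e)))
  det <- vapply(fits, detect_peak_20_40, logical(1))
  structure(list(n_epochs = n_epochs, n_detected = sum(det),
                 score = sum(det) / n_epochs, fits = fits, detected = det,
                 episodes = episodes),
            class = "rhythm_score")
}

#' @export
print.rhythm_score <- function(x, ...) {
  cat(sprintf("<rhythm_score> %d/%d epochs with a 20-40 Hz peak (score %.2f)\n",
              x$n_detected, x$n_epochs, x$score))
  invisible(x)
}

#' Attenuation of the rhythm score by glycine blockade
#'
#' `1 - score_str / score_ctrl`: 0 means no attenuation, 1 complete loss of
#' the 20-40 Hz rhythm under strychnine.
#'
#' @param score_ctrl control score (> 0); a `rhythm_score` or a number.
#' @param score_str strychnine score; a `rhythm_score` or a number.
#' @return numeric attenuation.
#' @export
attenuation <- function(score_ctrl, score_str) {
  s_c <- if (inherits(score_ctrl, "rhythm_score")) score_ctrl$score else score_ctrl
  s_s <- if (inherits(score_str, "rhythm_score")) score_str$score else score_str
  if (s_c <= 0) stop("attenuation is undefined when the control score is 0")
  1 - s_s / s_c
}

#' Rejection rule for arrhythmic control recordings
#'
#' Animals whose control-condition rhythm score falls below 0.5 are
#' considered arrhythmic and their recordings discarded, except animals
#' flagged exempt (the somite-1 at 5 dpf recordings, whose low control
#' scores were reproducible and retained).
#'
#' @param control_scores numeric vector, one control score per animal.
#' @param exempt_flags logical vector (recycled) marking exempt animals.
#' @param threshold rejection threshold (default 0.5).
#' @return list with `kept` (indices), `discarded` (indices),
#'   `discard_fraction`.
#' @export
apply_rejection_rule <- function(control_scores, exempt_flags = FALSE,
                                 threshold = 0.5) {
  exempt_flags <- rep_len(exempt_flags, length(control_scores))
  drop <- control_scores < threshold & !exempt_flags
  list(kept = which(!drop), discarded = which(drop),
       discard_fraction = mean(drop))
}
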