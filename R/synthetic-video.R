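#' Generate a synthetic swimming-fish video with ground truth
#'
#' Renders a head-embedded larva seen from above as a solid body silhouette
#' whose midline is a caudally traveling sine wave with amplitude growing
#' rostro-caudally (maximum tail bend very caudal), sampled at high speed
#' (default 500 fps). The amplitude ramps up over the first two beat cycles
#' so the first frame is the rest posture. Ground-truth midlines and the
#' ground-truth 30-segment bend-angle matrix are returned with the frames.
#'
#' @param wave_hz tail-beat (traveling-wave) frequency in Hz.
#' @param n_frames number of frames.
#' @param fps frame rate; must exceed `2 * wave_hz`.
#' @param amp_px peak lateral amplitude at the tail tip, in pixels.
#' @param amp_envelope function of normalized body position `s` in \[0, 1\]
#'   (0 = head) giving the relative amplitude; default a caudally growing
#'   quadratic with a small rostral floor.
#' @param img_shape frame size `c(rows, cols)`.
#' @param body_len_px body length along the image x axis, in pixels.
#' @param thickness_px full body thickness `c(head, tail)` in pixels; the
#'   thickness tapers linearly between them and every value must be >= 3
#'   (a thinner body has no defined skeleton).
#' @param n_waves number of spatial wavelengths on the body (default 1).
#' @param seed unused by the deterministic renderer but kept so specs are
#'   fully seeded.
#' @return list with `frames` (list of logical matrices), `midlines`
#'   (list of data frames `x`, `y` per frame), `angles` (ground-truth
#'   30 x n_frames bend-angle matrix), `fps`, `wave_hz`.
#' @export
generate_swim_video <- function(wave_hz = 30, n_frames = 250, fps = 500,
                                amp_px = 14,
                                amp_envelope = function(s) 0.15 + 0.85 * s^2,
                                img_shape = c(120, 260), body_len_px = 200,
                                thickness_px = c(16, 6), n_waves = 1,
                                seed = 1) {
  if (fps <= 2 * wave_hz)
    stop("`fps` must exceed twice the wave frequency")
  if (any(thickness_px < 3))
    stop("body thickness must be >= 3 px for the skeleton to be defined")
  nr <- img_shape[1]; nc <- img_shape[2]
  x0 <- round((nc - body_len_px) / 2)
  xs <- x0 + seq_len(body_len_px)          # body columns
  s <- (seq_along(xs) - 1) / (length(xs) - 1)
  yc <- nr / 2
  half <- (thickness_px[1] + (thickness_px[2] - thickness_px[1]) * s) / 2
  env <- amp_px * amp_envelope(s)
  t <- (seq_len(n_frames) - 1) / fps
  onset <- pmin(1, t * wave_hz / 2)        # rest at t = 0, full by 2 cycles
  rows <- seq_len(nr)
  frames <- vector("list", n_frames)
  midlines <- vector("list", n_frames)
  for (k in seq_len(n_frames)) {
    y <- yc + onset[k] * env * sin(2 * pi * (wave_hz * t[k] - n_waves * s))
    fr <- matrix(FALSE, nr, nc)
    fr[, xs] <- abs(outer(rows, y, "-")) <= rep(half, each = nr)
    frames[[k]] <- fr
    midlines[[k]] <- data.frame(x = xs, y = y)
  }
  rest <- data.frame(x = xs, y = rep(yc, length(xs)))
  angles <- body_angle_matrix(midlines, rest_midline = rest)
  list(frames = frames, midlines = midlines, angles = angles,
       fps = fps, wave_hz = wave_hz)
}

#' Write / read a logical or grayscale frame as plain-text PGM (P2)
#'
#' Plain PGM keeps the video stack fully text-based; one file per frame.
#'
#' @param frame logical or numeric matrix (values 0-255 after scaling).
#' @param path output file; for `read_pgm`, the file to read.
#' @param maxval maximum gray value (default 255).
#' @return `write_pgm` returns `path` invisibly; `read_pgm` returns an
#'   integer matrix.
#' @export
write_pgm <- function(frame, path, maxval = 255) {
  m <- if (is.logical(frame)) frame * maxval else round(frame)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(m), nrow(m)), as.character(maxval)), con)
  utils::write.table(m, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_pgm
#' @export
read_pgm <- function(path) {
  txt <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (txt[1] != "P2") stop("only plain (P2) PGM is supported")
  nc <- as.integer(txt[2]); nr <- as.integer(txt[3])
  vals <- as.integer(txt[-(1:4)])
  matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
}
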