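#' Binarize a video frame and clean the silhouette
#'
#' Thresholds a grayscale frame, dilates by one pixel to smooth the body
#' edge, fills interior holes, and keeps the largest connected component,
#' yielding a single solid fish silhouette.
#'
#' @param frame numeric or integer matrix (grayscale, ROI already applied),
#'   or a logical mask.
#' @param threshold binarization threshold; pixels strictly above it are
#'   foreground (default 0.5 for logical/0-1 frames).
#' @return logical matrix mask.
#' @export
binarize_and_clean <- function(frame, threshold = 0.5) {
  m <- if (is.logical(frame)) frame else frame > threshold
  if (!any(m)) stop("empty foreground: no fish in frame")
  m <- mask_dilate(m)
  m <- mask_fill_holes(m)
  mask_largest_component(m)
}

#' Extract the body midline from a silhouette mask
#'
#' Thins the mask to a skeleton (Zhang-Suen), prunes it to its longest
#' geodesic path (removing side branches), and orders the path from the
#' embedded head end to the tail.
#'
#' @param mask logical matrix from [binarize_and_clean()]; must be a single
#'   connected component.
#' @param head_side which image side the (fixed) head is on: `"left"`,
#'   `"right"`, `"top"`, `"bottom"`.
#' @return object of class `midline_frame`: data frame with ordered
#'   rostral-to-caudal pixel coordinates `x` (column), `y` (row).
#' @export
extract_midline <- function(mask, head_side = c("left", "right", "top", "bottom")) {
  head_side <- match.arg(head_side)
  if (!any(mask)) stop("empty mask")
  comp <- mask_largest_component(mask)
  if (sum(comp) != sum(mask)) stop("mask has more than one connected component")
  sk <- skeletonize(mask)
  idx <- which(sk)
  if (length(idx) < 2) stop("skeleton is degenerate (zero length)")
  nr <- nrow(mask)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  lab[idx] <- seq_along(idx)
  edges <- integer(0); wts <- numeric(0)
  for (d in list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))) {
    sh <- shift_mat(sk, d[1], d[2])
    both <- which(sk & sh)
    if (length(both)) {
      nb <- both - d[1] - d[2] * nr
      edges <- c(edges, rbind(lab[both], lab[nb]))
      wts <- c(wts, rep(sqrt(sum(d^2)), length(both)))
    }
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  igraph::E(g)$weight <- wts
  path <- igraph::get_diameter(g)            # longest geodesic path
  ord <- as.integer(path)
  rows <- ((idx - 1) %% nr) + 1
  cols <- ((idx - 1) %/% nr) + 1
  x <- cols[ord]; y <- rows[ord]
  flip <- switch(head_side,
                 left   = x[1] > x[length(x)],
                 right  = x[1] < x[length(x)],
                 top    = y[1] > y[length(y)],
                 bottom = y[1] < y[length(y)])
  if (flip) { x <- rev(x); y <- rev(y) }
  structure(data.frame(x = x, y = y), class = c("midline_frame", "data.frame"))
}

# Resample an ordered midline to n_pts points equally spaced in arc length,
# after light smoothing of the pixelated path.
resample_midline <- function(midline, n_pts, smooth_window = 5) {
  x <- midline$x; y <- midline$y
  if (smooth_window > 1 && length(x) > smooth_window) {
    k <- rep(1 / smooth_window, smooth_window)
    pad <- function(v) c(rep(v[1], smooth_window), v, rep(v[length(v)], smooth_window))
    sm <- function(v) {
      s <- stats::filter(pad(v), k, sides = 2)
      as.numeric(s[(smooth_window + 1):(smooth_window + length(v))])
    }
    x <- sm(x); y <- sm(y)
  }
  s <- c(0, cumsum(sqrt(diff(x)^2 + diff(y)^2)))
  if (s[length(s)] == 0) stop("midline has zero length")
  si <- seq(0, s[length(s)], length.out = n_pts)
  data.frame(x = stats::approx(s, x, si)$y, y = stats::approx(s, y, si)$y)
}

#' Per-segment bend angles relative to the rest posture
#'
#' Resamples the midline and the rest midline to `n_segments + 1` points
#' equally spaced in arc length, takes the arctangent of each segment's
#' local slope (finite difference of y with respect to x), and subtracts
#' the same quantity measured on the rest midline.
#'
#' @param midline,rest_midline `midline_frame`s (or data frames with
#'   `x`, `y`), ordered rostral to caudal.
#' @param n_segments number of body segments (default 30).
#' @param caudal_is_one if `TRUE` (default) normalized body position runs
#'   0 at the rostral end to 1 at the extreme caudal segment; `FALSE`
#'   flips the convention.
#' @return numeric vector of `n_segments` angles in radians, with the
#'   normalized segment positions in attribute `"positions"`.
#' @export
segment_angles <- function(midline, rest_midline, n_segments = 30,
                           caudal_is_one = TRUE) {
  if (nrow(midline) < n_segments + 1 || nrow(rest_midline) < n_segments + 1)
    stop(sprintf("midline must have at least %d points", n_segments + 1))
  m <- resample_midline(midline, n_segments + 1)
  r <- resample_midline(rest_midline, n_segments + 1)
  ang <- function(d) atan2(diff(d$y), diff(d$x))
  a <- ang(m) - ang(r)
  a <- atan2(sin(a), cos(a))           # wrap to (-pi, pi]
  pos <- (seq_len(n_segments) - 0.5) / n_segments
  if (!caudal_is_one) pos <- 1 - pos
  attr(a, "positions") <- pos
  a
}

#' Bend-angle matrix for a whole recording
#'
#' Runs [segment_angles()] on every frame's midline against a common rest
#' posture.
#'
#' @param midlines list of `midline_frame`s, one per frame.
#' @param rest_midline rest posture midline; default the first frame.
#' @param n_segments number of segments (default 30).
#' @param caudal_is_one position convention, see [segment_angles()].
#' @return `n_segments` x `n_frames` matrix of angles (radians), with
#'   normalized positions in attribute `"positions"`.
#' @export
body_angle_matrix <- function(midlines, rest_midline = midlines[[1]],
                              n_segments = 30, caudal_is_one = TRUE) {
  cols <- lapply(midlines, segment_angles, rest_midline = rest_midline,
                 n_segments = n_segments, caudal_is_one = caudal_is_one)
  m <- do.call(cbind, cols)
  attr(m, "positions") <- attr(cols[[1]], "positions")
  m
}

#' Per-segment FFT of the bend-angle time series
#'
#' Demeans each segment's angle time series and returns its FFT magnitude
#' over the non-negative frequencies, as plotted in per-segment frequency
#' heat maps.
#'
#' @param angle_matrix segments x frames matrix from [body_angle_matrix()].
#' @param fps video frame rate (default 500).
#' @return list with `positions`, `freqs_hz`, `magnitude`
#'   (segments x frequencies).
#' @export
per_segment_fft <- function(angle_matrix, fps = 500) {
  n <- ncol(angle_matrix)
  if (is.null(n) || n < 2) stop("need at least 2 frames")
  nf <- floor(n / 2) + 1
  mag <- t(apply(angle_matrix, 1, function(row)
    Mod(stats::fft(row - mean(row)))[seq_len(nf)]))
  list(positions = attr(angle_matrix, "positions"),
       freqs_hz = (seq_len(nf) - 1) / n * fps,
       magnitude = mag)
}

#' Full video-to-spectra kinematics pipeline
#'
#' Binarizes every frame, extracts and orders the midline, computes the
#' 30-segment bend angles against the rest posture, and returns the
#' per-segment FFT.
#'
#' @param frames list of grayscale matrices (or logical masks).
#' @param fps frame rate (default 500).
#' @param threshold binarization threshold.
#' @param n_segments number of body segments (default 30).
#' @param head_side side of the embedded head (default `"left"`).
#' @param rest_midline optional rest posture; default: midline of the first
#'   frame.
#' @param caudal_is_one position convention, see [segment_angles()].
#' @return list with `midlines`, `angles` (matrix), `fft`
#'   (see [per_segment_fft()]).
#' @export
kinematics_pipeline <- function(frames, fps = 500, threshold = 0.5,
                                n_segments = 30, head_side = "left",
                                rest_midline = NULL, caudal_is_one = TRUE) {
  midlines <- lapply(frames, function(f)
    extract_midline(binarize_and_clean(f, threshold), head_side = head_side))
  if (is.null(rest_midline)) rest_midline <- midlines[[1]]
  ang <- body_angle_matrix(midlines, rest_midline, n_segments = n_segments,
                           caudal_is_one = caudal_is_one)
  list(midlines = midlines, angles = ang, fft = per_segment_fft(ang, fps))
}
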