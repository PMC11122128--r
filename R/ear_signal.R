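#' Eye aspect ratio from six eye-contour landmarks
#'
#' EAR = (||p2 - p6|| + ||p3 - p5||) / (2 ||p1 - p4||): eye height over eye
#' width, where p1 and p4 are the eye corners, p2-p3 the upper lid and p5-p6
#' the lower lid. The ratio is scale-invariant and dips towards 0 during
#' blinks, but is blind to pupil position.
#'
#' @param points 6 x 2 matrix of (x, y) coordinates, rows p1..p6.
#' @return the eye aspect ratio (unitless, >= 0).
#' @export
compute_ear <- function(points) {
  points <- as.matrix(points)
  stopifnot(nrow(points) == 6, ncol(points) == 2)
  dist2 <- function(a, b) sqrt(sum((points[a, ] - points[b, ])^2))
  width <- dist2(1, 4)
  if (width <= 0) stop("zero eye width (p1 == p4)")
  (dist2(2, 6) + dist2(3, 5)) / (2 * width)
}

#' Per-frame EAR series from a landmark table
#'
#' @param landmarks data.frame with columns `p1x, p1y, ..., p6x, p6y` (one
#'   row per frame), e.g. the `landmarks` element of [generate_sequence()].
#' @return numeric vector of raw EAR values, `NA` where any landmark is
#'   missing.
#' @export
ear_series <- function(landmarks) {
  cols <- paste0("p", rep(1:6, each = 2), c("x", "y"))
  stopifnot(all(cols %in% names(landmarks)))
  m <- as.matrix(landmarks[, cols])
  vapply(seq_len(nrow(m)), function(i) {
    if (anyNA(m[i, ])) return(NA_real_)
    compute_ear(matrix(m[i, ], 6, 2, byrow = TRUE))
  }, numeric(1))
}

#' Linearly interpolate missing values in a series
#'
#' Interior gaps (e.g. failed landmark detections) are linearly interpolated
#' between the nearest observed neighbours; leading and trailing gaps are
#' filled with the nearest observed value.
#'
#' @param x numeric vector with `NA` gaps; at least one observed value.
#' @return gap-free numeric vector of the same length.
#' @export
interpolate_missing <- function(x) {
  obs <- which(!is.na(x))
  if (length(obs) == 0) stop("all values missing")
  if (length(obs) == length(x)) return(x)
  if (length(obs) == 1) return(rep(x[obs], length(x)))
  approx(obs, x[obs], xout = seq_along(x), rule = 2)$y
}

#' Robust per-session scaling of an EAR series
#'
#' Centres and scales by the median and (unscaled) median absolute deviation
#' of a calibration window, by default the first 20 s of the session, on the
#' assumption that participants are fully focused at the start. If the
#' calibration MAD is zero the MAD of the full session (about its own
#' median) is used; if that is also zero the series is centred only.
#'
#' @param x gap-free numeric EAR series.
#' @param fps frame rate.
#' @param calibration_sec length of the calibration window in seconds.
#' @return list with `values` (scaled series), `median`, `mad` (the scale
#'   actually used; 1 when centring only).
#' @export
robust_scale <- function(x, fps = 30, calibration_sec = 20) {
  stopifnot(!anyNA(x), length(x) >= 1, fps > 0, calibration_sec > 0)
  n_cal <- min(length(x), round(fps * calibration_sec))
  cal <- x[seq_len(n_cal)]
  med <- median(cal)
  s <- median(abs(cal - med))
  if (s == 0) s <- median(abs(x - median(x)))
  if (s == 0) s <- 1
  list(values = (x - med) / s, median = med, mad = s)
}

#' EAR-based temporal eye signal
#'
#' Baseline signal: the per-frame eye aspect ratio with missing values
#' linearly interpolated and robust per-session scaling applied.
#'
#' @inheritParams ear_series
#' @param fps frame rate.
#' @param scale logical; apply [robust_scale()] (default) or return the raw
#'   interpolated series.
#' @param calibration_sec passed to [robust_scale()].
#' @return a [temporal_signal()] with `source = "ear"`.
#' @export
extract_ear_signal <- function(landmarks, fps = 30, scale = TRUE,
                               calibration_sec = 20) {
  v <- interpolate_missing(ear_series(landmarks))
  if (scale) v <- robust_scale(v, fps = fps,
                               calibration_sec = calibration_sec)$values
  temporal_signal(v, fps = fps, source = "ear")
}
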