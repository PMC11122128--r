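#' Classify frames of an iris track as fixation or saccade
#'
#' A frame (from the second onwards) is a saccade if the horizontal iris
#' position moved by at least `threshold` pixels since the previous frame, a
#' fixation if it did not move at all, and unlabeled if it moved by a
#' non-zero sub-threshold amount (possible with sub-pixel tracking). The
#' first frame has no predecessor and is unlabeled. Missing positions are
#' linearly interpolated first.
#'
#' @param x per-frame horizontal iris coordinate (pixels); `NA` allowed.
#' @param threshold saccade displacement threshold in pixels (default 1).
#' @return character vector of `"fixation"`, `"saccade"`, `"unlabeled"`.
#' @export
classify_gaze_frames <- function(x, threshold = 1) {
  if (length(x) < 2) stop("need at least 2 frames")
  x <- interpolate_missing(x)
  dx <- abs(diff(x))
  lab <- ifelse(dx >= threshold, "saccade",
                ifelse(dx == 0, "fixation", "unlabeled"))
  c("unlabeled", lab)
}

#' Gaze summary features of an iris track
#'
#' Horizontal fixation percentage, saccade percentage and saccade velocity.
#' Percentages are counts of fixation/saccade frames over the k - 1 frames
#' that have a predecessor; velocity is the total absolute pixel movement
#' during saccade frames divided by the number of saccade frames (pooled
#' over all saccade frames by default, or averaged per continuous saccade
#' episode with `per_episode = TRUE`), and 0 when there are none.
#'
#' @inheritParams classify_gaze_frames
#' @param per_episode logical; average velocity within each continuous
#'   saccade episode and then across episodes.
#' @return data.frame with `fixation_pct`, `saccade_pct`,
#'   `saccade_velocity`.
#' @export
gaze_summary <- function(x, threshold = 1, per_episode = FALSE) {
  lab <- classify_gaze_frames(x, threshold)
  x <- interpolate_missing(x)
  k <- length(x)
  dx <- abs(diff(x))
  sac <- lab[-1] == "saccade"
  fix <- lab[-1] == "fixation"
  vel <- if (!any(sac)) 0 else if (!per_episode) {
    sum(dx[sac]) / sum(sac)
  } else {
    r <- rle(sac)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    ep <- which(r$values)
    mean(vapply(ep, function(e) mean(dx[starts[e]:ends[e]]), numeric(1)))
  }
  data.frame(fixation_pct = sum(fix) / (k - 1),
             saccade_pct = sum(sac) / (k - 1),
             saccade_velocity = vel)
}
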