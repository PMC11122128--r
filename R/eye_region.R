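#' Crop a standardized eye region from a frame
#'
#' Takes the axis-aligned bounding box of the eye landmarks, expands it by
#' `margin` times the box's own width/height on each side (25% in all
#' directions by default), clamps it to the frame borders, and resizes the
#' crop to `out_size` with bilinear interpolation.
#'
#' @param frame grayscale image matrix (rows = y, cols = x). A 3-channel
#'   array is converted to grayscale with Rec.601 luma weights.
#' @param eye_landmarks n x 2 matrix or data.frame of landmark (x, y)
#'   coordinates.
#' @param margin expansion per side as a proportion of the box dimension.
#' @param out_size output `c(height, width)` in pixels.
#' @return `out_size` numeric matrix.
#' @export
crop_eye <- function(frame, eye_landmarks, margin = 0.25,
                     out_size = c(96, 128)) {
  if (length(dim(frame)) == 3)
    frame <- 0.299 * frame[, , 1] + 0.587 * frame[, , 2] + 0.114 * frame[, , 3]
  lm <- as.matrix(eye_landmarks)
  stopifnot(ncol(lm) == 2, margin >= 0, length(out_size) == 2)
  if (anyNA(lm)) stop("missing landmark coordinates")
  x0 <- min(lm[, 1]); x1 <- max(lm[, 1])
  y0 <- min(lm[, 2]); y1 <- max(lm[, 2])
  bw <- x1 - x0; bh <- y1 - y0
  if (bw <= 0 || bh <= 0) stop("degenerate landmark bounding box")
  if (x0 < 1 || y0 < 1 || x1 > ncol(frame) || y1 > nrow(frame))
    message("eye landmarks extend outside the frame; crop clamped to borders")
  xs <- max(1, round(x0 - margin * bw)); xe <- min(ncol(frame), round(x1 + margin * bw))
  ys <- max(1, round(y0 - margin * bh)); ye <- min(nrow(frame), round(y1 + margin * bh))
  crop <- frame[ys:ye, xs:xe, drop = FALSE]
  resize_bilinear(crop, out_size[1], out_size[2])
}

# Bilinear resize; EBImage's first array dimension is treated as x, so the
# (rows = y) matrix convention here maps through unchanged row/col roles.
resize_bilinear <- function(m, out_h, out_w) {
  r <- EBImage::resize(m, w = out_h, h = out_w, filter = "bilinear")
  matrix(as.numeric(r), out_h, out_w)
}

#' Crop an eye region from every frame of a sequence
#'
#' Applies [crop_eye()] per frame. Frames whose landmarks are missing reuse
#' the previous crop and are flagged; a missing-landmark prefix is filled
#' from the first frame that has landmarks.
#'
#' @param frames height x width x k array, or list of matrices.
#' @param landmark_track list of per-frame landmark matrices (`NULL` or
#'   all-`NA` entries mark missing frames).
#' @param margin,out_size passed to [crop_eye()].
#' @param fps frame rate recorded on the output.
#' @return list with `frames` (out_h x out_w x k array), `fps`, and
#'   `filled` (logical vector flagging frames filled from a neighbour).
#' @export
crop_sequence <- function(frames, landmark_track, margin = 0.25,
                          out_size = c(96, 128), fps = 30) {
  if (is.list(frames)) frames <- simplify2array(frames)
  k <- dim(frames)[3]
  stopifnot(length(landmark_track) == k)
  missing <- vapply(landmark_track,
                    function(l) is.null(l) || all(is.na(l)), logical(1))
  if (all(missing)) stop("landmarks missing for every frame")
  out <- array(NA_real_, c(out_size[1], out_size[2], k))
  filled <- missing
  first_ok <- which(!missing)[1]
  last <- NULL
  for (i in seq_len(k)) {
    src <- if (missing[i]) NULL else i
    if (is.null(src) && is.null(last)) src <- first_ok  # leading gap
    if (!is.null(src)) {
      last <- crop_eye(frames[, , src], landmark_track[[src]],
                       margin = margin, out_size = out_size)
    }
    out[, , i] <- last
  }
  list(frames = out, fps = fps, filled = filled)
}
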