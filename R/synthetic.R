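#' Scene parameters for the synthetic eye renderer
#'
#' Defines the geometry and photometry of a rendered eye crop. The renderer
#' draws a light sclera ellipse (the palpebral fissure) on a darker skin
#' background, with a dark pupil disc clipped by the eyelid opening, and adds
#' i.i.d. Gaussian pixel noise. Frames are produced directly at eye-crop
#' resolution (default 96 x 128), the size consumed by the signal-extraction
#' pipeline.
#'
#' @param image_height,image_width frame size in pixels.
#' @param fps frame rate (frames/second).
#' @param duration sequence length in seconds.
#' @param eyelid_aperture_open eyelid opening (full height of the open eye,
#'   pixels); blinks ramp the aperture from this value to 0 and back.
#' @param eye_half_width horizontal semi-axis of the eyelid ellipse (pixels).
#' @param pupil_radius pupil disc radius (pixels).
#' @param iris_x_range interval (pixels) the horizontal iris-centre
#'   coordinate may occupy.
#' @param background_intensity,sclera_intensity,pupil_intensity grey levels
#'   in `[0, 255]` for skin, sclera and pupil.
#' @param noise_sigma standard deviation of additive Gaussian pixel noise
#'   (intensity units).
#' @param landmark_noise_sigma standard deviation of isotropic Gaussian
#'   jitter added to emitted landmark coordinates (pixels), emulating
#'   landmark-detector error.
#' @param seed integer seed; identical seeds give byte-identical sequences.
#' @return object of class `eye_scene_params`.
#' @export
eye_scene_params <- function(image_height = 96, image_width = 128, fps = 30,
                             duration = 20, eyelid_aperture_open = 48,
                             eye_half_width = 56, pupil_radius = 11,
                             iris_x_range = c(56.5, 72.5),
                             background_intensity = 90, sclera_intensity = 220,
                             pupil_intensity = 170, noise_sigma = 4,
                             landmark_noise_sigma = 0, seed = 1L) {
  stopifnot(image_height > 0, image_width > 0, fps > 0, duration > 0,
            eyelid_aperture_open > 0, eye_half_width > 0,
            pupil_radius > 0, pupil_radius < image_height / 2,
            length(iris_x_range) == 2, diff(iris_x_range) >= 0,
            iris_x_range[1] >= 1, iris_x_range[2] <= image_width,
            noise_sigma >= 0, landmark_noise_sigma >= 0)
  structure(list(image_height = image_height, image_width = image_width,
                 fps = fps, duration = duration,
                 eyelid_aperture_open = eyelid_aperture_open,
                 eye_half_width = eye_half_width, pupil_radius = pupil_radius,
                 iris_x_range = iris_x_range,
                 background_intensity = background_intensity,
                 sclera_intensity = sclera_intensity,
                 pupil_intensity = pupil_intensity, noise_sigma = noise_sigma,
                 landmark_noise_sigma = landmark_noise_sigma,
                 seed = as.integer(seed)),
            class = "eye_scene_params")
}

#' Behaviour regime for a synthetic sequence
#'
#' Encodes the oculomotor behaviour that distinguishes attentional states:
#' in the focused state the eye boundary is mostly stationary while the pupil
#' makes frequent horizontal saccades; the non-focused states show either a
#' long pupil fixation or head-motion-induced translation/rotation of the
#' whole eye region.
#'
#' @param label one of `"Focus"`, `"nonFocus_fixation"`,
#'   `"nonFocus_headmotion"`. Maps to binary class Focus = 1, others = 0.
#' @param blink_rate blinks per minute.
#' @param blink_duration frames per blink (symmetric linear close-open ramp;
#'   minimum 3).
#' @param saccade_rate horizontal saccades per minute (0 = fixate).
#' @param saccade_amplitude typical saccade jump (pixels).
#' @param fixation_dwell minimum inter-saccade dwell (frames).
#' @param head_translation_amplitude,head_rotation_amplitude amplitude of the
#'   sinusoidal whole-frame translation (pixels) and rotation (degrees).
#' @param head_period_s period of the head-motion sinusoid (seconds).
#' @return object of class `behavior_regime`.
#' @export
behavior_regime <- function(label = c("Focus", "nonFocus_fixation",
                                      "nonFocus_headmotion"),
                            blink_rate = 12, blink_duration = 9,
                            saccade_rate = 0, saccade_amplitude = 4,
                            fixation_dwell = 8,
                            head_translation_amplitude = 0,
                            head_rotation_amplitude = 0, head_period_s = 4) {
  label <- match.arg(label)
  stopifnot(blink_rate >= 0, blink_duration >= 3, saccade_rate >= 0,
            saccade_amplitude >= 0, fixation_dwell >= 1,
            head_translation_amplitude >= 0, head_rotation_amplitude >= 0,
            head_period_s > 0)
  structure(list(label = label, blink_rate = blink_rate,
                 blink_duration = as.integer(blink_duration),
                 saccade_rate = saccade_rate,
                 saccade_amplitude = saccade_amplitude,
                 fixation_dwell = as.integer(fixation_dwell),
                 head_translation_amplitude = head_translation_amplitude,
                 head_rotation_amplitude = head_rotation_amplitude,
                 head_period_s = head_period_s),
            class = "behavior_regime")
}

#' @rdname behavior_regime
#' @export
focus_regime <- function(...) {
  behavior_regime(label = "Focus", saccade_rate = 60, ...)
}

#' @rdname behavior_regime
#' @export
nonfocus_fixation_regime <- function(...) {
  behavior_regime(label = "nonFocus_fixation", saccade_rate = 0, ...)
}

#' @rdname behavior_regime
#' @export
nonfocus_headmotion_regime <- function(...) {
  behavior_regime(label = "nonFocus_headmotion", saccade_rate = 0,
                  head_translation_amplitude = 6,
                  head_rotation_amplitude = 5, ...)
}

#' @export
print.behavior_regime <- function(x, ...) {
  cat(sprintf("<behavior_regime> %s: %.3g blinks/min, %.3g saccades/min, head %.3g px / %.3g deg\n",
              x$label, x$blink_rate, x$saccade_rate,
              x$head_translation_amplitude, x$head_rotation_amplitude))
  invisible(x)
}

#' Render a single synthetic eye frame
#'
#' Draws the eyelid ellipse (vertical semi-axis `aperture / 2`), the pupil
#' disc centred at `iris_x` and clipped by the eyelid opening, adds Gaussian
#' noise, and clips to `[0, 255]`. Pixel (r, c) has centre coordinate
#' x = c, y = r; the eye centre sits at ((width + 1) / 2, (height + 1) / 2)
#' plus `shift`, and the whole geometry may be rotated by `angle` degrees
#' about the eye centre (head motion).
#'
#' @param aperture eyelid opening in pixels, in `[0, eyelid_aperture_open]`.
#' @param iris_x horizontal iris-centre coordinate in pixels.
#' @param params an [eye_scene_params()].
#' @param shift length-2 translation (x, y) of the eye centre, pixels.
#' @param angle in-plane rotation of the eye, degrees.
#' @param noise logical; set `FALSE` to render the noiseless scene.
#' @return `image_height` x `image_width` numeric matrix of grey levels.
#' @export
render_eye_frame <- function(aperture, iris_x, params, shift = c(0, 0),
                             angle = 0, noise = TRUE) {
  stopifnot(inherits(params, "eye_scene_params"))
  if (aperture < 0 || aperture > params$eyelid_aperture_open)
    stop("aperture out of range [0, eyelid_aperture_open]")
  if (iris_x < 1 || iris_x > params$image_width)
    stop("iris_x outside image width")
  h <- params$image_height; w <- params$image_width
  cx <- (w + 1) / 2 + shift[1]
  cy <- (h + 1) / 2 + shift[2]
  th <- angle * pi / 180
  xg <- matrix(seq_len(w), h, w, byrow = TRUE)
  yg <- matrix(seq_len(h), h, w)
  # eye-frame coordinates (u along the eye axis, v across it)
  u <- cos(th) * (xg - cx) + sin(th) * (yg - cy)
  v <- -sin(th) * (xg - cx) + cos(th) * (yg - cy)
  img <- matrix(params$background_intensity, h, w)
  if (aperture > 0) {
    a <- params$eye_half_width
    b <- aperture / 2
    sclera <- (u / a)^2 + (v / b)^2 <= 1
    img[sclera] <- params$sclera_intensity
    du <- u - (iris_x - (w + 1) / 2)
    pupil <- sclera & (du^2 + v^2 <= params$pupil_radius^2)
    img[pupil] <- params$pupil_intensity
  }
  if (noise && params$noise_sigma > 0)
    img <- img + rnorm(h * w, sd = params$noise_sigma)
  img[img < 0] <- 0
  img[img > 255] <- 255
  img
}

# Eye-contour landmarks for the current frame geometry, in image coordinates.
# Returns the 6-point EAR subset (p1 temporal corner, p2-p3 upper lid,
# p4 nasal corner, p5-p6 lower lid) and an 8-point contour used for cropping.
synthetic_landmarks <- function(aperture, iris_x, params, shift = c(0, 0),
                                angle = 0) {
  a <- params$eye_half_width
  b <- aperture / 2
  # points on the eyelid ellipse in the unrotated eye frame (y down)
  ear_u <- c(-a, -a / 3, a / 3, a, a / 3, -a / 3)
  ear_v <- c(0, -1, -1, 0, 1, 1) * b * sqrt(1 - (1 / 3)^2)
  cu <- c(-a, -a / 2, 0, a / 2, a, a / 2, 0, -a / 2)
  cv <- c(0, -0.866, -1, -0.866, 0, 0.866, 1, 0.866) * b
  th <- angle * pi / 180
  cx <- (params$image_width + 1) / 2 + shift[1]
  cy <- (params$image_height + 1) / 2 + shift[2]
  rot <- function(uu, vv) {
    cbind(x = cx + cos(th) * uu - sin(th) * vv,
          y = cy + sin(th) * uu + cos(th) * vv)
  }
  list(ear = rot(ear_u, ear_v), contour = rot(cu, cv))
}

# Schedule n non-overlapping blink onsets in frames 1..(k - d), seeded RNG
# assumed active. Falls back to even spacing if rejection sampling stalls.
schedule_blinks <- function(n, k, d) {
  if (n <= 0) return(integer(0))
  gap <- d + 5
  for (try in seq_len(200)) {
    on <- sort(sample.int(max(k - d, 1), n))
    if (n == 1 || min(diff(on)) >= gap) return(on)
  }
  round(seq(1, k - d, length.out = n))
}

# Symmetric linear close-open blink profile: multiplies the open aperture.
blink_profile <- function(d) {
  h <- floor(d / 2)
  abs(seq_len(d) - 1 - h) / h
}

#' Generate a synthetic eye-image sequence with ground truth
#'
#' Produces `round(fps * duration)` frames under the given behaviour regime,
#' together with a ground-truth log (blink apex frames, saccade frames,
#' per-frame aperture and iris position), per-frame synthetic landmarks
#' (6-point EAR subset plus 8-point contour) and the binary class label
#' (Focus = 1). Identical seeds reproduce identical output.
#'
#' @param regime a [behavior_regime()].
#' @param params an [eye_scene_params()].
#' @param render_frames logical; if `FALSE` only ground truth and landmarks
#'   are produced (fast path for behavioural statistics).
#' @return list with elements `frames` (height x width x k array or `NULL`),
#'   `log` (list: `blink_frames`, `saccade_frames`, `aperture_series`,
#'   `iris_x_series`), `landmarks` (data.frame with `frame_index`,
#'   `aperture`, `iris_x`, `p1x..p6y`, contour `c1x..c8y`, `label`),
#'   `label` (0/1), `fps`.
#' @export
generate_sequence <- function(regime, params, render_frames = TRUE) {
  stopifnot(inherits(regime, "behavior_regime"),
            inherits(params, "eye_scene_params"))
  k <- round(params$fps * params$duration)
  with_seed(params$seed, {
    open <- params$eyelid_aperture_open
    d <- regime$blink_duration
    n_blinks <- round(regime$blink_rate * params$duration / 60)
    onsets <- schedule_blinks(n_blinks, k, d)
    aperture <- rep(open, k)
    prof <- blink_profile(d)
    for (o in onsets) {
      idx <- o:(o + d - 1)
      keep <- idx <= k
      aperture[idx[keep]] <- open * prof[keep]
    }
    blink_frames <- onsets + floor(d / 2)

    # horizontal iris track: piecewise-constant with instantaneous jumps
    rng <- params$iris_x_range
    iris <- rep(runif(1, rng[1], rng[2]), k)
    if (regime$saccade_rate > 0 && diff(rng) > 0) {
      mean_gap <- 60 * params$fps / regime$saccade_rate
      t <- 1 + max(regime$fixation_dwell, round(rexp(1, 1 / mean_gap)))
      while (t <= k) {
        amp <- regime$saccade_amplitude * runif(1, 0.7, 1.3)
        cur <- iris[t - 1]
        lo_ok <- cur - amp >= rng[1]
        hi_ok <- cur + amp <= rng[2]
        dir <- if (lo_ok && hi_ok) sample(c(-1, 1), 1) else if (hi_ok) 1 else -1
        iris[t:k] <- min(max(cur + dir * amp, rng[1]), rng[2])
        t <- t + max(regime$fixation_dwell,
                     round(rexp(1, 1 / mean_gap)))
      }
    }
    saccade_frames <- which(diff(iris) != 0) + 1L

    # sinusoidal head motion (translation + rotation of the whole eye)
    tt <- seq_len(k) / params$fps
    phase <- runif(2, 0, 2 * pi)
    om <- 2 * pi / regime$head_period_s
    sx <- regime$head_translation_amplitude * sin(om * tt + phase[1])
    sy <- 0.5 * regime$head_translation_amplitude * sin(om * tt + phase[1] + pi / 3)
    ang <- regime$head_rotation_amplitude * sin(om * tt + phase[2])

    lm6 <- matrix(NA_real_, k, 12)
    lm8 <- matrix(NA_real_, k, 16)
    frames <- if (render_frames)
      array(NA_real_, c(params$image_height, params$image_width, k)) else NULL
    cache <- new.env(parent = emptyenv())
    for (i in seq_len(k)) {
      if (render_frames) {
        key <- sprintf("%.4f|%.4f|%.4f|%.4f|%.4f",
                       aperture[i], iris[i], sx[i], sy[i], ang[i])
        base <- cache[[key]]
        if (is.null(base)) {
          base <- render_eye_frame(aperture[i], iris[i], params,
                                   shift = c(sx[i], sy[i]), angle = ang[i],
                                   noise = FALSE)
          cache[[key]] <- base
        }
        f <- if (params$noise_sigma > 0)
          base + rnorm(length(base), sd = params$noise_sigma) else base
        f[f < 0] <- 0; f[f > 255] <- 255
        frames[, , i] <- f
      }
      lm <- synthetic_landmarks(aperture[i], iris[i], params,
                                shift = c(sx[i], sy[i]), angle = ang[i])
      lm6[i, ] <- as.vector(t(lm$ear))
      lm8[i, ] <- as.vector(t(lm$contour))
    }
    if (params$landmark_noise_sigma > 0) {
      lm6 <- lm6 + rnorm(length(lm6), sd = params$landmark_noise_sigma)
      lm8 <- lm8 + rnorm(length(lm8), sd = params$landmark_noise_sigma)
    }
    colnames(lm6) <- paste0("p", rep(1:6, each = 2), c("x", "y"))
    colnames(lm8) <- paste0("c", rep(1:8, each = 2), c("x", "y"))
    label <- as.integer(regime$label == "Focus")
    landmarks <- data.frame(frame_index = seq_len(k), aperture = aperture,
                            iris_x = iris, lm6, lm8, label = label)
    list(frames = frames,
         log = list(blink_frames = blink_frames,
                    saccade_frames = saccade_frames,
                    aperture_series = aperture, iris_x_series = iris),
         landmarks = landmarks, label = label, fps = params$fps)
  })
}

#' Generate a labelled collection of synthetic sequences
#'
#' Draws `n_sequences` sequences with a Focus proportion of `focus_fraction`
#' (default 5/6, i.e. the roughly 5:1 Focus:non-Focus imbalance of probed
#' online-learning recordings). Non-Focus sequences cycle through the
#' supplied non-focus regimes. Per-sequence seeds are derived
#' deterministically from `seed`.
#'
#' @param n_sequences number of sequences (>= 2).
#' @param focus_fraction proportion of Focus labels, in (0, 1).
#' @param params an [eye_scene_params()]; its `seed` field is overridden per
#'   sequence.
#' @param focus_regime,nonfocus_regimes the Focus regime and a list of
#'   non-Focus regimes.
#' @param seed master seed.
#' @param render_frames logical, as in [generate_sequence()].
#' @return list of [generate_sequence()] results, with attribute `labels`.
#' @export
generate_dataset <- function(n_sequences, focus_fraction = 5 / 6,
                             params = eye_scene_params(),
                             focus_regime = eyesvd::focus_regime(),
                             nonfocus_regimes = list(nonfocus_fixation_regime(),
                                                     nonfocus_headmotion_regime()),
                             seed = 1L, render_frames = TRUE) {
  if (n_sequences < 2) stop("n_sequences must be at least 2")
  if (focus_fraction <= 0 || focus_fraction >= 1)
    stop("focus_fraction must lie strictly between 0 and 1")
  n_focus <- round(n_sequences * focus_fraction)
  n_focus <- min(max(n_focus, 1), n_sequences - 1)
  labels <- c(rep(1L, n_focus), rep(0L, n_sequences - n_focus))
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n_sequences))
  out <- vector("list", n_sequences)
  j <- 0
  for (i in seq_len(n_sequences)) {
    p <- params
    p$seed <- seeds[i]
    reg <- if (labels[i] == 1L) focus_regime else {
      j <- j + 1
      nonfocus_regimes[[(j - 1) %% length(nonfocus_regimes) + 1]]
    }
    out[[i]] <- generate_sequence(reg, p, render_frames = render_frames)
  }
  attr(out, "labels") <- labels
  out
}
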