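#' Block grid for the energy matrix
#'
#' Tiles each frame into `rows` x `cols` rectangular blocks. The default
#' 6 x 8 grid gives 16 x 16-pixel blocks on a 96 x 128 crop, i.e. d = 48
#' blocks per frame, small relative to a 600-frame sequence so the thin SVD
#' of the energy matrix stays well-posed while each block is large enough to
#' average out pixel noise.
#'
#' @param rows,cols number of block rows and columns (`rows * cols >= 2`).
#' @return object of class `block_grid` with fields `rows`, `cols`, `d`.
#' @export
block_grid <- function(rows = 6, cols = 8) {
  stopifnot(rows >= 1, cols >= 1, rows * cols >= 2)
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 d = as.integer(rows * cols)), class = "block_grid")
}

#' Compute the block-energy matrix of an eye-crop sequence
#'
#' Each frame is divided into the blocks of `grid`; the energy of a block is
#' the sum of squared pixel intensities within it, with intensities taken on
#' the `[0, 1]` scale (8-bit values divided by 255) so energies are O(1) and
#' independent of integer vs floating-point input. Row i of the result is
#' the d-dimensional energy vector of frame i; blocks are ordered row-major
#' (block row, then block column). If the frame size is not divisible by the
#' grid, frames are cropped at the bottom/right to the largest tiling size.
#'
#' @param seq a height x width x k array of frames (grey levels in
#'   `[0, 255]`), or a list with element `frames`.
#' @param grid a [block_grid()].
#' @param intensity_scale divisor applied to pixel values before squaring
#'   (default 255; use 1 for data already in `[0, 1]`).
#' @return k x d non-negative matrix of class `energy_matrix`.
#' @export
compute_energy_matrix <- function(seq, grid = block_grid(),
                                  intensity_scale = 255) {
  if (is.list(seq) && !is.null(seq$frames)) seq <- seq$frames
  if (is.null(seq) || length(dim(seq)) != 3 || dim(seq)[3] < 1)
    stop("seq must be a non-empty height x width x k array of frames")
  stopifnot(inherits(grid, "block_grid"))
  h <- dim(seq)[1]; w <- dim(seq)[2]; k <- dim(seq)[3]
  bh <- h %/% grid$rows; bw <- w %/% grid$cols
  if (bh < 1 || bw < 1) stop("grid finer than the frame")
  hh <- bh * grid$rows; ww <- bw * grid$cols
  # block membership of each retained pixel, row-major over (brow, bcol)
  brow <- (seq_len(hh) - 1) %/% bh
  bcol <- (seq_len(ww) - 1) %/% bw
  block_of <- outer(brow * grid$cols, bcol, "+") + 1L       # hh x ww
  # k x (hh*ww) matrix of squared intensities, then pool per block
  sq <- matrix(seq[seq_len(hh), seq_len(ww), , drop = FALSE],
               nrow = hh * ww, ncol = k)
  sq <- (sq / intensity_scale)^2
  agg <- matrix(0, hh * ww, grid$d)
  agg[cbind(seq_len(hh * ww), as.vector(block_of))] <- 1
  E <- crossprod(sq, agg)                                    # k x d
  dimnames(E) <- NULL
  structure(E, class = c("energy_matrix", class(E)))
}

#' Thin SVD of an energy matrix
#'
#' Decomposes E = U diag(sigma) V' with p = min(k, d) columns. The left
#' singular vectors are the temporal basis of the sequence: u1 carries the
#' low-rank (static scene) component, the higher-rank vectors carry sparse or
#' high-frequency temporal change. Each singular-vector pair is sign-fixed so
#' that the largest-magnitude element of the left vector is positive, making
#' the decomposition deterministic.
#'
#' @param E k x d non-negative matrix (k, d >= 2).
#' @return list of class `svd_result` with `u` (k x p), `d` (singular values,
#'   descending), `v` (d x p).
#' @export
decompose_energy <- function(E) {
  E <- unclass(E)
  if (!is.matrix(E) || nrow(E) < 2 || ncol(E) < 2)
    stop("E must be a matrix with at least 2 rows and 2 columns")
  if (!all(is.finite(E))) stop("E contains non-finite entries")
  s <- svd(E)
  for (j in seq_along(s$d)) {
    i <- which.max(abs(s$u[, j]))
    if (s$u[i, j] < 0) {
      s$u[, j] <- -s$u[, j]
      s$v[, j] <- -s$v[, j]
    }
  }
  structure(list(u = s$u, d = s$d, v = s$v), class = "svd_result")
}

#' Scale and smooth a raw singular vector into a temporal signal
#'
#' Min-max scales the vector to `[0, 1]` (a constant vector maps to the
#' information-free midpoint 0.5), then applies a centred moving-average
#' filter of length `window` with edge truncation (shorter averages at the
#' boundaries) to suppress outliers and noise.
#'
#' @param v numeric vector (a raw left singular vector).
#' @param window moving-average length in frames (>= 1; default 5, about
#'   167 ms at 30 fps).
#' @param fps frame rate recorded on the output signal.
#' @return a [temporal_signal()] with `source = "svd"`.
#' @export
preprocess_signal <- function(v, window = 5, fps = 30) {
  if (!all(is.finite(v))) stop("non-finite values in singular vector")
  n <- length(v)
  if (window < 1 || window > n) stop("window must be in [1, length(v)]")
  rng <- max(v) - min(v)
  x <- if (rng <= .Machine$double.eps * max(1, max(abs(v))))
    rep(0.5, n) else (v - min(v)) / rng
  temporal_signal(moving_average(x, window), fps = fps, source = "svd")
}

# Centred moving average with edge truncation.
moving_average <- function(x, window) {
  if (window == 1) return(x)
  n <- length(x)
  h1 <- floor((window - 1) / 2)
  h2 <- window - 1 - h1
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h1, 1)
  hi <- pmin(seq_len(n) + h2, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Select the singular vector carrying the eye-change signal
#'
#' Candidates are the higher-rank left singular vectors u2..u_max_rank (u1 is
#' the low-rank static component). Each candidate is smoothed with the same
#' centred moving average used for the output signal, mean-removed, and
#' transformed by FFT; the winner maximises the largest single-bin magnitude
#' at frequencies inside `band`. By default the comparison weights each
#' candidate by its singular value, i.e. it is performed on sigma_j * u_j,
#' the actual rank-j contribution to the energy matrix, so that vectors
#' describing large temporal energy changes outrank noise-dominated vectors
#' of near-zero singular value (min-max scaling each candidate first would
#' erase exactly that amplitude information; set
#' `scale_before_select = TRUE` for that variant). Ties break toward the
#' lowest rank. Candidates whose singular value is negligible relative to
#' sigma1 contribute nothing to E and are treated as information-free (flat
#' midpoint signal). The winning vector is returned min-max scaled and
#' smoothed via [preprocess_signal()].
#'
#' @param svd_res an [decompose_energy()] result.
#' @param fps frame rate of the originating sequence.
#' @param band frequency interval (Hz) searched for the peak; default
#'   `c(0.5, 15)` excludes DC/illumination drift and covers blink and
#'   saccade transients at 30 fps.
#' @param max_rank highest candidate rank (default 10).
#' @param window moving-average length passed to [preprocess_signal()].
#' @param scale_before_select logical; if `TRUE`, min-max scale each
#'   candidate before the FFT comparison instead of weighting by its
#'   singular value.
#' @return list with `rank` (selected index j*), `signal` (the preprocessed
#'   [temporal_signal()] of the winner), and `peaks` (per-candidate in-band
#'   peak magnitudes).
#' @export
select_signal_vector <- function(svd_res, fps, band = c(0.5, 15),
                                 max_rank = 10, window = 5,
                                 scale_before_select = FALSE) {
  stopifnot(inherits(svd_res, "svd_result"), length(band) == 2,
            band[1] > 0, band[2] <= fps / 2, band[1] < band[2], max_rank >= 2)
  p <- length(svd_res$d)
  if (p < 2) stop("decomposition has no candidate beyond the low-rank vector")
  cand <- 2:min(max_rank, p)
  k <- nrow(svd_res$u)
  freqs <- (seq_len(k) - 1) * fps / k
  in_band <- freqs >= band[1] & freqs <= band[2] & seq_len(k) <= floor(k / 2) + 1
  degenerate <- logical(length(cand))
  peaks <- numeric(length(cand))
  for (m in seq_along(cand)) {
    j <- cand[m]
    if (svd_res$d[j] <= 1e-10 * svd_res$d[1]) {
      degenerate[m] <- TRUE
      peaks[m] <- 0
      next
    }
    x <- if (scale_before_select) {
      preprocess_signal(svd_res$u[, j], window = window, fps = fps)$values
    } else {
      moving_average(svd_res$d[j] * svd_res$u[, j], window)
    }
    x <- x - mean(x)
    mag <- Mod(fft(x))
    peaks[m] <- if (any(in_band)) max(mag[in_band]) else 0
  }
  best <- which.max(peaks)   # which.max takes the first maximum: lowest rank
  sig <- if (degenerate[best])
    temporal_signal(rep(0.5, k), fps = fps, source = "svd")
  else
    preprocess_signal(svd_res$u[, cand[best]], window = window, fps = fps)
  sig$selected_rank <- cand[best]
  list(rank = cand[best], signal = sig,
       peaks = stats::setNames(peaks, paste0("u", cand)))
}

#' Extract the SVD-based temporal eye signal from an eye-crop sequence
#'
#' End-to-end pipeline: block-energy matrix, thin SVD, preprocessing of the
#' higher-rank left singular vectors, and frequency-based selection of the
#' vector that best represents temporal eye change.
#'
#' @param seq frames array (or list with `frames`), as in
#'   [compute_energy_matrix()].
#' @param fps frame rate of the sequence.
#' @inheritParams compute_energy_matrix
#' @inheritParams select_signal_vector
#' @return a [temporal_signal()] with `source = "svd"` and the selected rank
#'   recorded in `selected_rank`.
#' @export
extract_svd_signal <- function(seq, fps = 30, grid = block_grid(),
                               band = c(0.5, 15), window = 5, max_rank = 10,
                               intensity_scale = 255) {
  E <- compute_energy_matrix(seq, grid, intensity_scale = intensity_scale)
  s <- decompose_energy(E)
  select_signal_vector(s, fps = fps, band = band, max_rank = max_rank,
                       window = window)$signal
}
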