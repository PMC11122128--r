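# Independent naive reimplementations used as oracles. These deliberately use
# explicit loops and textbook formulas, not the package's vectorised paths.

# Per-pixel, per-block energy summation by nested loops.
naive_energy_matrix <- function(frames, rows, cols, scale = 255) {
  h <- dim(frames)[1]; w <- dim(frames)[2]; k <- dim(frames)[3]
  bh <- h %/% rows; bw <- w %/% cols
  E <- matrix(0, k, rows * cols)
  for (i in seq_len(k)) {
    for (br in seq_len(rows)) {
      for (bc in seq_len(cols)) {
        b <- (br - 1) * cols + bc
        acc <- 0
        for (y in ((br - 1) * bh + 1):(br * bh)) {
          for (x in ((bc - 1) * bw + 1):(bc * bw)) {
            acc <- acc + (frames[y, x, i] / scale)^2
          }
        }
        E[i, b] <- acc
      }
    }
  }
  E
}

# Centred moving average by direct windowed mean.
naive_moving_average <- function(x, window) {
  n <- length(x)
  h1 <- floor((window - 1) / 2)
  h2 <- window - 1 - h1
  vapply(seq_len(n), function(i) {
    mean(x[max(1, i - h1):min(n, i + h2)])
  }, numeric(1))
}

# Full pipeline on a tiny sequence: loops + full SVD + plain arithmetic.
naive_svd_signal <- function(frames, fps, rows, cols, band = c(0.5, 15),
                             window = 5, max_rank = 10) {
  E <- naive_energy_matrix(frames, rows, cols)
  s <- svd(E, nu = nrow(E), nv = ncol(E))
  p <- min(dim(E))
  for (j in seq_len(p)) {                       # same sign convention
    i <- which.max(abs(s$u[, j]))
    if (s$u[i, j] < 0) s$u[, j] <- -s$u[, j]
  }
  cand <- 2:min(max_rank, p)
  k <- nrow(E)
  freqs <- (seq_len(k) - 1) * fps / k
  in_band <- freqs >= band[1] & freqs <= band[2] & seq_len(k) <= floor(k / 2) + 1
  peaks <- numeric(length(cand))
  for (m in seq_along(cand)) {
    j <- cand[m]
    if (s$d[j] <= 1e-10 * s$d[1]) { peaks[m] <- 0; next }
    x <- naive_moving_average(s$d[j] * s$u[, j], window)
    x <- x - mean(x)
    mag <- Mod(fft(x))
    peaks[m] <- if (any(in_band)) max(mag[in_band]) else 0
  }
  j <- cand[which.max(peaks)]
  v <- s$u[, j]
  if (s$d[j] <= 1e-10 * s$d[1]) return(list(rank = j, values = rep(0.5, k)))
  rng <- max(v) - min(v)
  sc <- if (rng <= .Machine$double.eps * max(1, max(abs(v))))
    rep(0.5, k) else (v - min(v)) / rng
  list(rank = j, values = naive_moving_average(sc, window))
}

# Locations of the n highest prominent excursions of a signal from its median.
signal_excursions <- function(values, n, min_distance = 10) {
  x <- abs(values - median(values))
  pk <- pracma::findpeaks(x, npeaks = n, minpeakdistance = min_distance,
                          sortstr = TRUE)
  sort(pk[, 2])
}

# In-band spectral power of a mean-removed series.
band_power <- function(values, fps, lo = 0.5, hi = 15) {
  x <- values - mean(values)
  n <- length(x)
  nb <- floor(n / 2) + 1
  mag <- Mod(fft(x))[seq_len(nb)]
  f <- (seq_len(nb) - 1) * fps / n
  sum(mag[f >= lo & f <= hi]^2)
}

# Rank-based AUROC (Mann-Whitney), independent of pROC.
rank_auroc <- function(labels, scores) {
  r <- rank(scores)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Small deterministic test sequence (blinks + saccades) shared across files.
demo_sequence <- function(seed = 7, duration = 20, regime = focus_regime()) {
  generate_sequence(regime, eye_scene_params(seed = seed, duration = duration))
}

# Direct-formula oracle for every statistical feature.
naive_stat <- function(x, bins = 10) {
  n <- length(x)
  m <- sum(x) / n
  m2 <- sum((x - m)^2) / n
  ent <- if (max(x) == min(x)) 0 else {
    br <- seq(min(x), max(x), length.out = bins + 1)
    cnt <- hist(x, breaks = br, plot = FALSE)$counts
    p <- cnt[cnt > 0] / n
    -sum(p * log2(p)) / log2(bins)
  }
  c(abs_energy = sum(x^2), entropy = ent,
    iqr = unname(quantile(x, 0.75) - quantile(x, 0.25)),
    max = max(x), min = min(x), mean = m,
    mean_abs_dev = sum(abs(x - m)) / n,
    median = median(x), median_abs_dev = median(abs(x - median(x))),
    std = sqrt(m2), var = m2, peak_to_peak = max(x) - min(x),
    rms = sqrt(sum(x^2) / n),
    kurtosis = if (m2 > 0) (sum((x - m)^4) / n) / m2^2 - 3 else 0,
    skewness = if (m2 > 0) (sum((x - m)^3) / n) / m2^1.5 else 0)
}

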