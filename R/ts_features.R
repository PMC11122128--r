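#' Statistical features of a temporal signal
#'
#' The fifteen statistical descriptors used throughout the attentional-state
#' pipeline: absolute energy (sum of squares), histogram-based Shannon
#' entropy, interquartile range, max, min, mean, mean absolute deviation,
#' median, median absolute deviation (unscaled), standard deviation
#' (population denominator n), variance, peak-to-peak distance, root mean
#' square, excess kurtosis and skewness (moment estimators g2, g1).
#'
#' Entropy is computed from a 10-bin equal-width histogram over the signal
#' range, normalized by log2(10) so it lies in `[0, 1]`; a constant signal
#' has entropy 0. All definitions are pinned so the feature set is bit-stable
#' across runs.
#'
#' @param s a [temporal_signal()] or numeric vector of length >= 4.
#' @param entropy_bins number of histogram bins for the entropy estimate.
#' @return named numeric vector of 15 features.
#' @export
statistical_features <- function(s, entropy_bins = 10) {
  x <- signal_values(s)
  if (length(x) < 4) stop("signal too short (need >= 4 samples)")
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  sdev <- sqrt(m2)
  kur <- if (m2 > 0) mean((x - m)^4) / m2^2 - 3 else 0
  ske <- if (m2 > 0) mean((x - m)^3) / m2^1.5 else 0
  c(abs_energy = sum(x^2),
    entropy = shannon_entropy(x, entropy_bins),
    iqr = unname(diff(quantile(x, c(0.25, 0.75)))),
    max = max(x), min = min(x), mean = m,
    mean_abs_dev = mean(abs(x - m)),
    median = median(x),
    median_abs_dev = median(abs(x - median(x))),
    std = sdev, var = m2,
    peak_to_peak = max(x) - min(x),
    rms = sqrt(mean(x^2)),
    kurtosis = kur, skewness = ske)
}

# Normalized histogram Shannon entropy in [0, 1]; constant input -> 0.
shannon_entropy <- function(x, bins = 10) {
  if (max(x) == min(x)) return(0)
  cuts <- seq(min(x), max(x), length.out = bins + 1)
  cnt <- tabulate(findInterval(x, cuts, rightmost.closed = TRUE), nbins = bins)
  p <- cnt[cnt > 0] / length(x)
  -sum(p * log2(p)) / log2(bins)
}

# One-sided magnitude spectrum of the raw (unwindowed) signal.
# Returns frequencies (Hz), magnitudes, and the one-sided periodogram PSD
# (interior bins doubled), shared by all spectral features.
one_sided_spectrum <- function(x, fps) {
  n <- length(x)
  nb <- floor(n / 2) + 1
  mag <- Mod(fft(x))[seq_len(nb)]
  freqs <- (seq_len(nb) - 1) * fps / n
  psd <- mag^2 / (fps * n)
  if (nb > 2) {
    inner <- 2:(nb - 1)
    if (n %% 2 == 0) inner <- inner else inner <- 2:nb
    psd[inner] <- 2 * psd[inner]
  }
  list(freqs = freqs, mag = mag, psd = psd)
}

# Frequency at which the cumulative magnitude reaches q of its total.
cumulative_frequency <- function(freqs, mag, q) {
  tot <- sum(mag)
  if (tot == 0) return(0)
  freqs[which(cumsum(mag) >= q * tot)[1]]
}

#' Spectral features of a temporal signal
#'
#' Seventeen spectral descriptors computed from the one-sided FFT of the raw
#' (unwindowed) signal, all sharing the same spectrum: maximum of the power
#' spectral density; maximum frequency (95% cumulative-magnitude quantile);
#' median frequency (50% quantile); power bandwidth (width of the central
#' 95%-power frequency interval); fundamental frequency (first local maximum
#' of the magnitude spectrum above DC); spectral centroid, decrease,
#' distance, entropy, kurtosis, skewness, slope, spread and variation; and
#' wavelet energy, entropy and variance from a Ricker (Mexican-hat)
#' continuous wavelet transform, expanded per scale.
#'
#' Moment-type features (centroid, spread, skewness, kurtosis) treat the
#' normalized magnitude spectrum as a probability distribution over
#' frequency. Spectral distance is the summed difference between the
#' straight line from 0 to the total cumulative magnitude and the cumulative
#' magnitude curve; spectral slope is the OLS slope of magnitude on
#' frequency; spectral variation is one minus the normalized correlation
#' between consecutive magnitude bins; spectral entropy is the normalized
#' Shannon entropy of the PSD. Wavelet energy at a scale is the RMS of the
#' CWT coefficients, wavelet variance their population variance, and wavelet
#' entropy the Shannon entropy of per-scale absolute-coefficient mass.
#'
#' @param s a [temporal_signal()] or numeric vector of length >= 8.
#' @param fps frame rate (taken from the signal when available).
#' @param wavelet_scales integer CWT scales (default 1:9, covering the
#'   scale-5 and scale-8 features retained by the attention analysis).
#' @return named numeric vector (14 scalar features + per-scale wavelet
#'   features + wavelet entropy).
#' @export
spectral_features <- function(s, fps = NULL, wavelet_scales = 1:9) {
  x <- signal_values(s)
  if (is.null(fps)) {
    if (!inherits(s, "temporal_signal")) stop("fps must be supplied")
    fps <- s$fps
  }
  if (length(x) < 8) stop("signal too short (need >= 8 samples)")
  sp <- one_sided_spectrum(x, fps)
  f <- sp$freqs; mag <- sp$mag; psd <- sp$psd
  tot <- sum(mag)
  p <- if (tot > 0) mag / tot else rep(0, length(mag))
  centroid <- sum(f * p)
  mu2 <- sum((f - centroid)^2 * p)
  spread <- sqrt(mu2)
  skew <- if (mu2 > 0) sum((f - centroid)^3 * p) / mu2^1.5 else 0
  kurt <- if (mu2 > 0) sum((f - centroid)^4 * p) / mu2^2 else 0
  # decrease: average slope of magnitude relative to the first bin
  dec_den <- sum(mag[-1])
  decrease <- if (dec_den > 0)
    sum((mag[-1] - mag[1]) / seq_len(length(mag) - 1)) / dec_den else 0
  cum <- cumsum(mag)
  ref <- seq(0, cum[length(cum)], length.out = length(cum))
  distance <- sum(ref - cum)
  pp <- if (sum(psd) > 0) psd / sum(psd) else psd
  pp <- pp[pp > 0]
  sentropy <- if (length(pp) > 1) -sum(pp * log2(pp)) / log2(length(psd)) else 0
  slope <- if (var(f) > 0) sum((f - mean(f)) * (mag - mean(mag))) / sum((f - mean(f))^2) else 0
  m1 <- mag[-length(mag)]; m2 <- mag[-1]
  den <- sqrt(sum(m1^2)) * sqrt(sum(m2^2))
  variation <- if (den > 0) 1 - sum(m1 * m2) / den else 0
  # power bandwidth: central 95% of total PSD power
  cp <- cumsum(psd)
  bandwidth <- if (cp[length(cp)] > 0) {
    lo <- f[which(cp >= 0.025 * cp[length(cp)])[1]]
    hi <- f[which(cp >= 0.975 * cp[length(cp)])[1]]
    hi - lo
  } else 0
  out <- c(max_power_spectrum = max(psd),
           maximum_frequency = cumulative_frequency(f, mag, 0.95),
           median_frequency = cumulative_frequency(f, mag, 0.50),
           power_bandwidth = bandwidth,
           fundamental_frequency = fundamental_frequency(f, mag),
           spectral_centroid = centroid,
           spectral_decrease = decrease,
           spectral_distance = distance,
           spectral_entropy = sentropy,
           spectral_kurtosis = kurt,
           spectral_skewness = skew,
           spectral_slope = slope,
           spectral_spread = spread,
           spectral_variation = variation)
  c(out, wavelet_features(x, wavelet_scales))
}

# First local maximum of the magnitude spectrum above DC, ignoring bins below
# 1% of the spectral maximum (numerical noise on line spectra); falls back to
# the largest non-DC bin, and 0 for a flat spectrum.
fundamental_frequency <- function(f, mag) {
  n <- length(mag)
  if (n < 3) return(0)
  floor_mag <- 0.01 * max(mag)
  for (i in 2:(n - 1)) {
    if (mag[i] > floor_mag && mag[i] > mag[i - 1] && mag[i] >= mag[i + 1])
      return(f[i])
  }
  if (max(mag[-1]) > min(mag[-1])) f[1 + which.max(mag[-1])] else 0
}

# Ricker (Mexican-hat) wavelet sampled at integer offsets, scale a.
ricker_wavelet <- function(points, a) {
  t <- seq_len(points) - (points + 1) / 2
  A <- 2 / (sqrt(3 * a) * pi^0.25)
  A * (1 - (t / a)^2) * exp(-t^2 / (2 * a^2))
}

# CWT row for one scale: same-length convolution of x with the wavelet.
cwt_scale <- function(x, a) {
  n <- length(x)
  L <- min(10 * a, n)
  w <- ricker_wavelet(L, a)
  full <- convolve(x, rev(w), type = "open")   # true convolution, length n + L - 1
  start <- floor((L - 1) / 2) + 1
  full[start:(start + n - 1)]
}

wavelet_features <- function(x, scales) {
  cw <- vapply(scales, function(a) cwt_scale(x, a), numeric(length(x)))
  energy <- sqrt(colMeans(cw^2))
  wvar <- colMeans(cw^2) - colMeans(cw)^2
  mass <- colSums(abs(cw))
  went <- if (sum(mass) > 0) {
    pr <- mass[mass > 0] / sum(mass)
    -sum(pr * log2(pr))
  } else 0
  stats::setNames(c(energy, went, wvar),
                  c(paste0("wavelet_energy_", scales), "wavelet_entropy",
                    paste0("wavelet_var_", scales)))
}

#' Extract a feature vector from a temporal signal
#'
#' @inheritParams spectral_features
#' @param domain `"statistical"`, `"spectral"`, or `"both"`.
#' @return named numeric feature vector.
#' @export
signal_features <- function(s, domain = c("statistical", "spectral", "both"),
                            fps = NULL, wavelet_scales = 1:9) {
  domain <- match.arg(domain)
  out <- numeric(0)
  if (domain %in% c("statistical", "both"))
    out <- c(out, statistical_features(s))
  if (domain %in% c("spectral", "both"))
    out <- c(out, spectral_features(s, fps = fps,
                                    wavelet_scales = wavelet_scales))
  out
}
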