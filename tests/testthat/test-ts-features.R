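test_that("statistical features match the direct-formula oracle", {
  for (seed in 1:10) {
    set.seed(seed)
    x <- rnorm(200, sd = runif(1, 0.1, 5))
    expect_equal(statistical_features(x), naive_stat(x), tolerance = 1e-10)
  }
})

test_that("statistical features handle closed forms and degenerate input", {
  const <- statistical_features(rep(2, 20))
  expect_equal(unname(const[c("std", "var", "peak_to_peak", "entropy",
                              "kurtosis", "skewness")]), rep(0, 6))
  alt <- statistical_features(rep(c(0, 1), 25))
  expect_equal(unname(alt["mean"]), 0.5)
  expect_equal(unname(alt["rms"]), sqrt(0.5))
  expect_equal(unname(alt["peak_to_peak"]), 1)
  expect_error(statistical_features(c(1, 2, 3)), "too short")
})

test_that("spectral moments localise a pure sinusoid", {
  fps <- 30; n <- 300
  x <- sin(2 * pi * 3 * (0:(n - 1)) / fps)
  f <- spectral_features(x, fps = fps)
  bin <- fps / n
  expect_lt(abs(f[["median_frequency"]] - 3), bin + 1e-9)
  expect_lt(f[["spectral_spread"]], bin + 1e-9)
  expect_lt(abs(f[["spectral_centroid"]] - 3), bin + 1e-9)
  expect_lt(abs(f[["fundamental_frequency"]] - 3), bin + 1e-9)
})

test_that("DC-only signal has a zero-frequency spectrum", {
  f <- spectral_features(rep(4, 64), fps = 32)
  expect_equal(f[["spectral_centroid"]], 0)
  expect_equal(f[["median_frequency"]], 0)
  expect_equal(f[["maximum_frequency"]], 0)
})

test_that("white-noise maximum frequency sits near 95% of Nyquist", {
  set.seed(5)
  mf <- replicate(20, {
    x <- rnorm(600)
    spectral_features(x, fps = 30)[["maximum_frequency"]]
  })
  expect_lt(abs(mean(mf) - 0.95 * 15) / (0.95 * 15), 0.05)
})

test_that("spectral features match an independent direct computation", {
  set.seed(11)
  x <- rnorm(128)
  fps <- 32
  f <- spectral_features(x, fps = fps)
  n <- length(x)
  nb <- n / 2 + 1
  mag <- abs(fft(x))[1:nb]
  fr <- (0:(nb - 1)) * fps / n
  expect_equal(f[["maximum_frequency"]],
               fr[min(which(cumsum(mag) >= 0.95 * sum(mag)))])
  expect_equal(f[["spectral_centroid"]], sum(fr * mag) / sum(mag),
               tolerance = 1e-12)
  ctr <- sum(fr * mag) / sum(mag)
  expect_equal(f[["spectral_spread"]],
               sqrt(sum((fr - ctr)^2 * mag / sum(mag))), tolerance = 1e-12)
  expect_equal(f[["spectral_slope"]], unname(coef(lm(mag ~ fr))[2]),
               tolerance = 1e-10)
  expect_equal(f[["spectral_decrease"]],
               sum((mag[-1] - mag[1]) / (seq_len(nb - 1))) / sum(mag[-1]),
               tolerance = 1e-12)
  expect_equal(f[["spectral_variation"]],
               1 - sum(mag[-nb] * mag[-1]) /
                 (sqrt(sum(mag[-nb]^2)) * sqrt(sum(mag[-1]^2))),
               tolerance = 1e-12)
  cum <- cumsum(mag)
  expect_equal(f[["spectral_distance"]],
               sum(seq(0, cum[nb], length.out = nb) - cum), tolerance = 1e-9)
})

test_that("wavelet features match a direct convolution oracle", {
  set.seed(4)
  x <- rnorm(100)
  f <- spectral_features(x, fps = 25, wavelet_scales = c(5, 8))
  for (a in c(5, 8)) {
    L <- min(10 * a, length(x))
    t <- seq_len(L) - (L + 1) / 2
    w <- 2 / (sqrt(3 * a) * pi^0.25) * (1 - (t / a)^2) * exp(-t^2 / (2 * a^2))
    full <- numeric(length(x) + L - 1)
    for (i in seq_along(x)) for (j in seq_len(L))
      full[i + j - 1] <- full[i + j - 1] + x[i] * w[j]
    st <- floor((L - 1) / 2) + 1
    cc <- full[st:(st + length(x) - 1)]
    expect_equal(f[[paste0("wavelet_energy_", a)]], sqrt(mean(cc^2)),
                 tolerance = 1e-8)
    expect_equal(f[[paste0("wavelet_var_", a)]], mean(cc^2) - mean(cc)^2,
                 tolerance = 1e-8)
  }
})

test_that("features obey amplitude equivariance and time-reversal invariance", {
  set.seed(9)
  x <- rnorm(120)
  a <- 3.7
  s1 <- statistical_features(x); s2 <- statistical_features(a * x)
  expect_equal(s2[["abs_energy"]], a^2 * s1[["abs_energy"]], tolerance = 1e-10)
  f1 <- spectral_features(x, fps = 30); f2 <- spectral_features(a * x, fps = 30)
  expect_equal(f2[["spectral_centroid"]], f1[["spectral_centroid"]],
               tolerance = 1e-10)
  expect_equal(f2[["median_frequency"]], f1[["median_frequency"]])
  fr <- spectral_features(rev(x), fps = 30)
  for (nm in c("max_power_spectrum", "maximum_frequency", "median_frequency",
               "spectral_centroid", "spectral_spread", "spectral_entropy"))
    expect_equal(fr[[nm]], f1[[nm]], tolerance = 1e-9)
})

test_that("fps is taken from a temporal_signal and required otherwise", {
  sig <- temporal_signal(runif(64), fps = 30, source = "svd")
  expect_silent(spectral_features(sig))
  expect_error(spectral_features(runif(64)), "fps")
})
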