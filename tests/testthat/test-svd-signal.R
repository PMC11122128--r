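test_that("energy matrix matches the brute-force per-pixel oracle", {
  set.seed(42)
  frames <- array(runif(8 * 12 * 5, 0, 255), c(8, 12, 5))
  E <- compute_energy_matrix(frames, block_grid(2, 3))
  expect_equal(dim(E), c(5, 6))
  expect_equal(unclass(E), naive_energy_matrix(frames, 2, 3),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(E >= 0))
})

test_that("energy matrix handles degenerate intensities", {
  zeros <- array(0, c(8, 8, 3))
  expect_true(all(compute_energy_matrix(zeros, block_grid(2, 2)) == 0))
  # constant intensity 1 on the [0,1] scale: 16x16 blocks of ones squared
  ones <- array(1, c(96, 128, 2))
  E <- compute_energy_matrix(ones, block_grid(6, 8), intensity_scale = 1)
  expect_true(all(E == 256))
  expect_error(compute_energy_matrix(array(1, c(4, 4, 0))), "non-empty")
})

test_that("SVD satisfies reconstruction, ordering and Gram-eigenvalue identities", {
  set.seed(7)
  E <- matrix(runif(10 * 6), 10, 6)
  s <- decompose_energy(E)
  recon <- s$u %*% diag(s$d) %*% t(s$v)
  expect_lt(norm(E - recon, "F"), 1e-8 * norm(E, "F"))
  expect_true(all(diff(s$d) <= 0))
  expect_equal(crossprod(s$u), diag(6), tolerance = 1e-10)
  ev <- sort(eigen(crossprod(E), symmetric = TRUE)$values, decreasing = TRUE)
  expect_equal(s$d^2, ev, tolerance = 1e-8)
  # rank-1 input
  r1 <- outer(1:9, seq(0.5, 3, length.out = 5))
  s1 <- decompose_energy(r1)
  expect_lt(s1$d[2], 1e-10 * s1$d[1])
  expect_error(decompose_energy(matrix(c(1, NA, 2, 3), 2, 2)), "non-finite")
})

test_that("singular values are invariant to block permutation", {
  set.seed(3)
  frames <- array(runif(12 * 12 * 8, 0, 255), c(12, 12, 8))
  E <- compute_energy_matrix(frames, block_grid(3, 4))
  perm <- sample(ncol(E))
  expect_equal(decompose_energy(E)$d, decompose_energy(E[, perm])$d,
               tolerance = 1e-10)
})

test_that("preprocessing scales, smooths and handles degenerate input", {
  ramp <- seq(-1, 1, length.out = 11)
  s <- preprocess_signal(ramp, window = 1)
  expect_equal(s$values, seq(0, 1, length.out = 11))
  expect_equal(preprocess_signal(rep(3.2, 10), window = 3)$values, rep(0.5, 10))
  x <- c(0, 1, 0, 1, 0)
  expect_equal(preprocess_signal(x, window = 3)$values,
               naive_moving_average(x, 3))
  set.seed(1)
  r <- rnorm(50)
  expect_equal(preprocess_signal(r, window = 4)$values,
               naive_moving_average((r - min(r)) / diff(range(r)), 4))
  expect_error(preprocess_signal(c(1, NA, 2)), "non-finite")
})

test_that("selection picks the vector with the largest in-band peak", {
  k <- 120; fps <- 30
  t <- (seq_len(k) - 1) / fps
  unit <- function(v) v / sqrt(sum(v^2))
  # u3 is a pure 2 Hz sinusoid; all other candidates constant
  U <- cbind(unit(rep(1, k)), unit(rep(1, k)), unit(sin(2 * pi * 2 * t)),
             unit(rep(1, k)))
  s <- structure(list(u = U, d = c(10, 5, 4, 3), v = diag(4)),
                 class = "svd_result")
  expect_equal(select_signal_vector(s, fps)$rank, 3)
  # all candidates constant: tie broken toward rank 2
  Uc <- cbind(unit(rep(1, k)), unit(rep(1, k)), unit(rep(2, k)))
  sc <- structure(list(u = Uc, d = c(3, 2, 1), v = diag(3)),
                  class = "svd_result")
  expect_equal(select_signal_vector(sc, fps)$rank, 2)
  # 1 Hz amplitude 1.0 beats 2 Hz amplitude 0.4
  U2 <- cbind(unit(rep(1, k)), sin(2 * pi * t), 0.4 * sin(2 * pi * 2 * t))
  s2 <- structure(list(u = U2, d = c(10, 1, 1), v = diag(3)),
                  class = "svd_result")
  expect_equal(select_signal_vector(s2, fps)$rank, 2)
  expect_error(select_signal_vector(
    structure(list(u = U[, 1, drop = FALSE], d = 1, v = diag(1)),
              class = "svd_result"), fps), "no candidate")
})

test_that("tiny-sequence pipeline matches the naive loop + full-SVD oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    frames <- array(runif(8 * 12 * 12, 0, 255), c(8, 12, 12))
    got <- extract_svd_signal(frames, fps = 30, grid = block_grid(2, 3),
                              window = 3)
    ref <- naive_svd_signal(frames, 30, 2, 3, window = 3)
    expect_equal(got$selected_rank, ref$rank)
    expect_equal(got$values, ref$values, tolerance = 1e-8)
  }
})

test_that("signal is invariant to intensity scaling and candidate sign flips", {
  sq <- demo_sequence(seed = 2, duration = 4)
  sig <- extract_svd_signal(sq$frames, fps = 30)
  half <- extract_svd_signal(sq$frames * 0.5, fps = 30)
  expect_equal(sig$values, half$values, tolerance = 1e-8)
  # energy scales by c^2
  E1 <- compute_energy_matrix(sq$frames)
  E2 <- compute_energy_matrix(sq$frames * 0.5)
  expect_equal(unclass(E2), unclass(E1) * 0.25, tolerance = 1e-10)
  # sign flip of a singular vector leaves spectral magnitudes unchanged
  v <- decompose_energy(E1)$u[, 2]
  a <- preprocess_signal(v)$values
  b <- preprocess_signal(-v)$values
  expect_equal(Mod(fft(a - mean(a))), Mod(fft(b - mean(b))), tolerance = 1e-8)
})

test_that("static scene yields a flat signal at zero noise", {
  p <- eye_scene_params(seed = 3, noise_sigma = 0, duration = 4)
  sq <- generate_sequence(nonfocus_fixation_regime(blink_rate = 0), p)
  sig <- extract_svd_signal(sq$frames, fps = 30)
  expect_lt(sd(sig$values), 1e-6)
})
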