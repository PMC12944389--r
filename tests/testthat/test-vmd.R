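test_that("two well-separated tones are recovered as two narrowband modes", {
  s <- two_tone_signal()
  m <- vmd_decompose(s, vmd_params(K = 2, alpha = 2000))
  expect_lt(abs(m$omega[1] - 50), 2)
  expect_lt(abs(m$omega[2] - 200), 2)
  # each mode's dominant FFT peak sits at its center frequency
  expect_lt(abs(fft_peak_hz(m$modes[, 1], m$fs) - m$omega[1]), 2)
  expect_lt(abs(fft_peak_hz(m$modes[, 2], m$fs) - m$omega[2]), 2)
  # reconstruction error
  err <- sqrt(sum((s$samples - vmd_reconstruct(m))^2) / sum(s$samples^2))
  expect_lt(err, 0.05)
  # cross-mode leakage: mode-1 energy near 200 Hz is < 5% of mode-1 energy
  leak <- band_energy(m$modes[, 1], m$fs, 200, 10) / sum(Mod(fft(m$modes[, 1]))^2)
  expect_lt(leak, 0.05)
})

test_that("a constant signal collapses to a single DC mode", {
  s <- semg_signal(rep(2.5, 1000), fs_default)
  m <- vmd_decompose(s, vmd_params(K = 1, alpha = 2000))
  expect_lt(sqrt(sum((m$modes[, 1] - 2.5)^2) / sum(rep(2.5, 1000)^2)), 1e-2)
  expect_lt(m$omega[1], 1)
})

test_that("mode summation and input validation behave", {
  m <- make_modeset(cbind(tone(50, 1), -tone(50, 1)))
  expect_equal(vmd_reconstruct(m), rep(0, nrow(m$modes)))
  single <- make_modeset(tone(100, 1))
  expect_identical(vmd_reconstruct(single), single$modes[, 1])

  expect_error(vmd_decompose(semg_signal(c(1, NaN, 3, 4), 100) , vmd_params(1, 100)))
  expect_error(vmd_decompose(semg_signal(1:6, 100), vmd_params(4, 100)),
               "too short")
  expect_error(vmd_params(K = 0, alpha = 100))
  expect_error(vmd_params(K = 2, alpha = -1))
})

test_that("larger alpha never widens a mode's spectral bandwidth", {
  s <- two_tone_signal()
  second_moment <- function(u, fs) {
    n <- length(u)
    p <- (Mod(stats::fft(u))^2)[seq_len(n %/% 2 + 1)]
    f <- (seq_along(p) - 1) * fs / n
    mu <- sum(f * p) / sum(p)
    sum((f - mu)^2 * p) / sum(p)
  }
  m1 <- vmd_decompose(s, vmd_params(2, 2000))
  m2 <- vmd_decompose(s, vmd_params(2, 4000))
  for (k in 1:2)
    expect_lte(second_moment(m2$modes[, k], m2$fs),
               second_moment(m1$modes[, k], m1$fs) * (1 + 1e-8))
})

test_that("with dual ascent the reconstruction residual keeps shrinking", {
  s <- two_tone_signal()
  m <- vmd_decompose(s, vmd_params(2, 2000, tau = 0.5))
  expect_true(m$converged)
  h <- m$residual_history
  last <- tail(h, 10)
  expect_true(all(diff(last) <= 1e-8))
})

test_that("center-frequency estimates are robust across the alpha range", {
  s <- two_tone_signal()
  lo <- vmd_decompose(s, vmd_params(2, 500))
  hi <- vmd_decompose(s, vmd_params(2, 2000))
  expect_true(all(abs(lo$omega - hi$omega) < 5))
})
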