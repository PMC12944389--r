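test_that("default record matches the acquisition protocol arithmetic", {
  s <- generate_keystroke_semg(synthetic_config(seed = 1))
  expect_length(s$samples, 37500)          # 25 s at 1500 Hz
  expect_identical(s$rest_span, c(0L, 7500L))  # 5 s rest prefix

  a <- generate_keystroke_semg(synthetic_config(seed = 1))
  b <- generate_keystroke_semg(synthetic_config(seed = 1))
  expect_identical(a$samples, b$samples)
  c2 <- generate_keystroke_semg(synthetic_config(seed = 2))
  expect_false(identical(a$samples, c2$samples))
})

test_that("rest is quiet relative to every burst core", {
  s <- generate_keystroke_semg(synthetic_config(seed = 3))
  env <- attr(s, "burst_envelope")
  rest_rms <- sqrt(mean(s$samples[1:7500]^2))
  core <- env > 0.5 * max(env)
  # per-burst cores: split core samples by contiguity
  runs <- rle(core)
  idx <- cumsum(runs$lengths)
  starts <- c(1, head(idx, -1) + 1)[runs$values]
  ends <- idx[runs$values]
  expect_gte(length(starts), 20)
  for (j in seq_along(starts)) {
    burst_rms <- sqrt(mean(s$samples[starts[j]:ends[j]]^2))
    expect_lt(rest_rms, 0.1 * burst_rms)
  }
})

test_that("bursts are high-duty-cycle and spectrally in-band", {
  s <- generate_keystroke_semg(synthetic_config(seed = 4))
  env <- attr(s, "burst_envelope")
  task <- 7501:length(env)
  duty <- mean(env[task] > 0.05 * max(env))
  expect_gte(duty, 0.25)

  pure <- generate_keystroke_semg(synthetic_config(seed = 4,
                                                   baseline_noise_rms = 0))
  core <- which(attr(pure, "burst_envelope") > 0.05 * max(env))
  frac <- band_energy_fraction(pure$samples[core], pure$fs, 20, 450)
  expect_gte(frac, 0.9)
})

test_that("noise injection hits the requested input SNR exactly", {
  s <- generate_keystroke_semg(synthetic_config(seed = 6))
  for (lev in c(0, 5, 10, 15)) {
    noisy <- add_wgn(s, lev, seed = 9)
    expect_equal(snr_db(s$samples, noisy$samples), lev, tolerance = 0.01)
  }
  n1 <- add_wgn(s, 10, seed = 1)
  n2 <- add_wgn(s, 10, seed = 2)
  expect_false(identical(n1$samples, n2$samples))
  expect_equal(snr_db(s$samples, n1$samples), snr_db(s$samples, n2$samples))

  expect_identical(add_wgn(s, Inf)$samples, s$samples)
  expect_error(add_wgn(semg_signal(c(0, 0), 100), 10), "all-zero")
})

test_that("configuration invariants are enforced", {
  expect_error(synthetic_config(burst_duration = 1.2), "beat period")
  expect_error(synthetic_config(burst_band = c(20, 900)))
  cfg <- synthetic_config()
  expect_equal(cfg$fs * (cfg$rest_seconds + cfg$n_keystrokes * 60 / cfg$bpm),
               37500)
})
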