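test_that("the Hilbert envelope tracks instantaneous amplitude", {
  x <- tone(100, 2)
  a <- envelope(x)
  interior <- a[150:(length(a) - 150)]
  expect_lt(max(abs(interior - 1)), 0.05)

  expect_equal(envelope(rep(0, 64)), rep(0, 64))
  expect_equal(envelope(3.5 * x), 3.5 * envelope(x), tolerance = 1e-9)
})

test_that("envelope entropy attains its closed-form bounds", {
  # constant envelope of length 1024: exactly 10 bits
  expect_equal(envelope_entropy(rep(1, 1024)), 10, tolerance = 1e-6)
  expect_equal(envelope_entropy(rep(1, 1024), is_envelope = TRUE), 10,
               tolerance = 1e-6)
  # point mass: zero bits
  expect_identical(envelope_entropy(c(rep(0, 511), 1, rep(0, 512)),
                                    is_envelope = TRUE), 0)
  # scale invariance
  withr::with_seed(3, x <- rnorm(512))
  expect_equal(envelope_entropy(x), envelope_entropy(100 * x),
               tolerance = 1e-9)
  # bounds for arbitrary input
  e <- envelope_entropy(x)
  expect_gte(e, 0)
  expect_lte(e, log2(512))
  expect_warning(ez <- envelope_entropy(rep(0, 256)), "zero-mass")
  expect_equal(ez, 8)
})

test_that("burst structure has lower envelope entropy than white noise", {
  n <- 1000
  hann <- 0.5 * (1 - cos(2 * pi * (0:200) / 200))
  wins <- 0
  for (s in 1:100) {
    withr::with_seed(s, {
      burst <- 0.01 * rnorm(n)
      burst[400:600] <- burst[400:600] + hann * rnorm(201)
      noise <- rnorm(n)
    })
    if (envelope_entropy(burst) < envelope_entropy(noise)) wins <- wins + 1
  }
  expect_gte(wins, 95)
})

test_that("energy gating excludes trivial low-energy modes from the minimum", {
  hann <- 0.5 * (1 - cos(2 * pi * (0:200) / 200))
  withr::with_seed(11, {
    burst <- 0.01 * rnorm(1000)
    burst[400:600] <- burst[400:600] + hann * rnorm(201)
  })
  spike <- c(rep(0, 499), 1e-4, rep(0, 500))  # ~zero energy, near-zero entropy
  ms <- make_modeset(cbind(burst, spike))
  expect_equal(mmee_fitness(ms), envelope_entropy(burst))
  expect_lt(envelope_entropy(spike), envelope_entropy(burst))  # gate matters

  single <- make_modeset(burst)
  expect_equal(mmee_fitness(single), envelope_entropy(burst))
  dup <- make_modeset(cbind(burst, burst))
  expect_equal(mmee_fitness(dup), mmee_fitness(single))
  # scale invariance of the gated fitness
  ms2 <- make_modeset(cbind(burst, spike) * -7)
  expect_equal(mmee_fitness(ms2), mmee_fitness(ms), tolerance = 1e-9)
})
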