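# brute-force partition oracle: walk the series, cut at strict sign changes
# of the zero-carried sign sequence
partition_oracle <- function(x) {
  s <- sign(x)
  cur <- 0
  lab <- integer(length(x))
  seg <- 1L
  for (i in seq_along(x)) {
    if (s[i] != 0 && cur != 0 && s[i] != cur) seg <- seg + 1L
    if (s[i] != 0) cur <- s[i]
    lab[i] <- seg
  }
  lab
}

test_that("zero-crossing partition matches an exhaustive oracle", {
  cases <- list(
    c(1, 1, -1, -1, 1),
    rep(1, 7),
    c(1, -1, 1, -1, 1, -1),
    c(0, 0, 2, 0, -3, 0, 0, 1),
    c(-0.5, 0, 0.5, 1, 0, -1)
  )
  for (x in cases) {
    p <- zero_cross_partition(x)
    lab <- partition_oracle(x)
    expect_identical(nrow(p), max(lab))
    expect_identical(p$start, as.integer(c(0, which(diff(lab) == 1))))
    expect_identical(p$end, as.integer(c(which(diff(lab) == 1), length(x))))
    for (j in seq_len(nrow(p))) {
      seg <- (p$start[j] + 1):p$end[j]
      expect_identical(abs(p$extremum_value[j]), max(abs(x[seg])))
      expect_true(p$extremum_index[j] >= p$start[j] &&
                    p$extremum_index[j] < p$end[j])
    }
  }
  # the worked example: three intervals with extrema 1, -1, 1
  p <- zero_cross_partition(c(1, 1, -1, -1, 1))
  expect_identical(p$start, c(0L, 2L, 4L))
  expect_identical(p$end, c(2L, 4L, 5L))
  expect_identical(p$extremum_value, c(1, -1, 1))
  # alternating signs: six one-sample intervals
  expect_identical(nrow(zero_cross_partition(c(1, -1, 1, -1, 1, -1))), 6L)
})

test_that("random series always tile into sign-homogeneous intervals", {
  for (s in 1:25) {
    withr::with_seed(s, x <- round(rnorm(50), 1))
    p <- zero_cross_partition(x)
    expect_identical(p$start[1], 0L)
    expect_identical(p$end[nrow(p)], length(x))
    if (nrow(p) > 1)
      expect_identical(p$start[-1], p$end[-nrow(p)])
  }
})

test_that("the rest-based sigma estimator is calibrated for Gaussian noise", {
  hits <- 0
  for (s in 1:200) {
    withr::with_seed(4000 + s, r <- rnorm(7500))
    sig <- estimate_sigma(r, c(0, 7500))
    if (abs(sig - 1) <= 0.03) hits <- hits + 1
  }
  expect_gte(hits, 190)

  expect_equal(estimate_sigma(rep(0.6745, 100), c(0, 100)), 1)
  expect_identical(estimate_sigma(rep(0, 100), c(0, 100)), 0)
  expect_error(estimate_sigma(1:10, NULL), "rest")
})

test_that("threshold formulas evaluate to their closed forms", {
  expect_equal(improved_threshold(2, 7, 1), 2 * sqrt(2 * log(7)))
  expect_equal(improved_threshold(1, 7500, 0.3), 0.3 * sqrt(2 * log(7500)))
  expect_identical(improved_threshold(0, 100, 0.5), 0)
  expect_error(improved_threshold(1, 1, 0.3), "n_rest")
  expect_error(improved_threshold(1, 100, 0), "C")

  expect_equal(universal_threshold(1, 2), sqrt(2 * log(2)))
  expect_identical(universal_threshold(0, 1000), 0)
  expect_gt(universal_threshold(1, 1e6), universal_threshold(1, 1e3))
  expect_error(universal_threshold(1, 1))
})

test_that("interval thresholding follows the per-interval decision rule", {
  x <- c(0.5, 0.4, -2, -1, 0.3)   # extrema: 0.5 | -2 | 0.3
  p <- zero_cross_partition(x)
  hard <- interval_threshold(x, p, 1, "hard")
  expect_equal(hard, c(0, 0, -2, -1, 0))
  soft <- interval_threshold(x, p, 1, "soft")
  expect_equal(soft, c(0, 0, -1, -0.5, 0))  # factor (2-1)/2 = 0.5

  # T = 0 is the identity for both operators
  expect_equal(interval_threshold(x, p, 0, "hard"), x)
  expect_equal(interval_threshold(x, p, 0, "soft"), x)

  expect_error(interval_threshold(x[1:4], p, 1, "hard"), "match")
})

test_that("thresholding never adds energy and hard dominates soft", {
  for (s in 1:20) {
    withr::with_seed(100 + s, x <- rnorm(200))
    p <- zero_cross_partition(x)
    for (T in c(0, 0.5, 1, 2, 5)) {
      h <- interval_threshold(x, p, T, "hard")
      so <- interval_threshold(x, p, T, "soft")
      expect_lte(sum(h^2), sum(x^2))
      expect_lte(sum(so^2), sum(x^2))
      expect_true(all(abs(h) >= abs(so) - 1e-12))
    }
  }
})

test_that("rest detection recovers a known quiet prefix", {
  s <- generate_keystroke_semg(synthetic_config(seed = 5))
  span <- detect_rest(s)
  true_span <- s$rest_span
  overlap <- max(0, min(span[2], true_span[2]) - max(span[1], true_span[1]))
  expect_gte(overlap / (span[2] - span[1]), 0.9)

  z <- semg_signal(rep(0, 3000), fs_default)
  expect_identical(detect_rest(z, window = 0.5), c(0L, 3000L))

  withr::with_seed(6, loud <- semg_signal(rnorm(6000), fs_default))
  span2 <- detect_rest(loud)
  expect_true(span2[1] >= 0 && span2[2] <= 6000 && span2[1] < span2[2])
})
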