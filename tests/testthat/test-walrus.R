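sphere_cfg <- function(seed) {
  wo_config(pop_size = 20, max_iter = 50, bounds = rbind(c(-5, -5), c(5, 5)),
            seed = seed)
}

test_that("the optimizer solves smooth test functions from most seeds", {
  ok_sphere <- sum(vapply(1:20, function(s) {
    wo_minimize(function(x) sum(x^2), sphere_cfg(s))$best_fitness <= 1e-2
  }, logical(1)))
  expect_gte(ok_sphere, 19)

  ok_quad <- sum(vapply(1:20, function(s) {
    r <- wo_minimize(function(x) (x - 3)^2,
                     wo_config(pop_size = 10, max_iter = 30,
                               bounds = rbind(0, 10), seed = s))
    abs(r$best_position - 3) <= 0.1
  }, logical(1)))
  expect_gte(ok_quad, 18)
})

test_that("elitism keeps the fitness history non-increasing", {
  for (s in 1:10) {
    r <- wo_minimize(function(x) sum(cos(3 * x) + x^2), sphere_cfg(s))
    expect_true(all(diff(r$history) <= 0))
    expect_identical(r$best_fitness, r$history[length(r$history)])
  }
})

test_that("every evaluated position stays inside the box", {
  lo <- c(-1, 2); hi <- c(1, 5)
  seen_ok <- TRUE
  obj <- function(x) {
    if (any(x < lo - 1e-12) || any(x > hi + 1e-12)) seen_ok <<- FALSE
    sum((x - c(0, 3))^2)
  }
  r <- wo_minimize(obj, wo_config(pop_size = 8, max_iter = 25,
                                  bounds = rbind(lo, hi), seed = 4))
  expect_true(seen_ok)
  expect_identical(r$evaluations, 8L * 26L)
})

test_that("a flat landscape and a fixed seed are handled exactly", {
  cfg <- wo_config(pop_size = 6, max_iter = 12,
                   bounds = rbind(c(0, 0), c(1, 1)), seed = 9)
  r <- wo_minimize(function(x) 1.0, cfg)
  expect_identical(r$best_fitness, 1.0)
  expect_true(all(r$history == 1.0))

  a <- wo_minimize(function(x) sum(x^2), cfg)
  b <- wo_minimize(function(x) sum(x^2), cfg)
  expect_identical(a$best_position, b$best_position)
  expect_identical(a$history, b$history)
})

test_that("non-finite objectives are quarantined, not propagated", {
  # NaN on half the box: those positions never become the best
  r <- wo_minimize(function(x) if (x[1] < 0) NaN else sum(x^2),
                   sphere_cfg(2))
  expect_true(is.finite(r$best_fitness))
  expect_error(
    wo_minimize(function(x) NaN,
                wo_config(pop_size = 4, max_iter = 2,
                          bounds = rbind(0, 1), seed = 1)),
    "non-finite")
})

test_that("integer-masked dimensions are reported as integers", {
  r <- wo_minimize(function(x) (x[1] - 2.7)^2 + x[2]^2,
                   wo_config(pop_size = 10, max_iter = 20,
                             bounds = rbind(c(0, -1), c(10, 1)),
                             integer_dims = c(TRUE, FALSE), seed = 5))
  expect_identical(r$best_position[1], round(r$best_position[1]))
  expect_equal(r$best_position[1], 3)
})
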