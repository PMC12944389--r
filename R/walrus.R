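#' Walrus optimizer configuration
#'
#' Controls for the walrus optimizer ([wo_minimize()]), a population
#' metaheuristic that mimics walrus herd behavior: a danger signal that
#' decays over iterations gates the population between a migration phase
#' (global exploration: individuals step along the difference of two random
#' herd members) and a reproduction phase (exploitation: role-based updates
#' for male, female and juvenile individuals, with a Levy-flight flee rule
#' for juveniles when the safety signal is low).
#'
#' @param pop_size Population size N (>= 4).
#' @param max_iter Number of iterations I (>= 1).
#' @param bounds Two-row matrix (or 2-element list/vector per dimension):
#'   row 1 lower, row 2 upper bound of the search box.
#' @param integer_dims Logical mask; marked dimensions are rounded to the
#'   nearest integer at objective evaluation and in the reported optimum
#'   (the search itself stays continuous).
#' @param role_fractions Proportions of (male, female, juvenile)
#'   individuals; must sum to 1.
#' @param levy_exponent Stability index of the Levy flights used by the
#'   juvenile flee rule (Mantegna's algorithm).
#' @param seed Optional RNG seed; a fixed seed makes the whole search
#'   deterministic.
#' @return An object of class `wo_config`.
#' @export
wo_config <- function(pop_size = 10, max_iter = 15, bounds = NULL,
                      integer_dims = NULL,
                      role_fractions = c(0.45, 0.45, 0.10),
                      levy_exponent = 1.5, seed = NULL) {
  pop_size <- as.integer(pop_size)
  max_iter <- as.integer(max_iter)
  if (is.na(pop_size) || pop_size < 4L) stop("`pop_size` must be >= 4")
  if (is.na(max_iter) || max_iter < 1L) stop("`max_iter` must be >= 1")
  if (length(role_fractions) != 3L || any(role_fractions < 0) ||
      abs(sum(role_fractions) - 1) > 1e-8)
    stop("`role_fractions` must be 3 non-negative values summing to 1")
  if (!is.finite(levy_exponent) || levy_exponent <= 0 || levy_exponent > 2)
    stop("`levy_exponent` must lie in (0, 2]")
  structure(list(pop_size = pop_size, max_iter = max_iter, bounds = bounds,
                 integer_dims = integer_dims,
                 role_fractions = role_fractions,
                 levy_exponent = levy_exponent, seed = seed),
            class = "wo_config")
}

check_bounds <- function(bounds) {
  b <- if (is.matrix(bounds)) bounds else matrix(unlist(bounds), nrow = 2L)
  # equal bounds pin a dimension (degenerate but valid search box)
  if (nrow(b) != 2L || any(!is.finite(b)) || any(b[1L, ] > b[2L, ]))
    stop("`bounds` must give finite lower <= upper per dimension")
  b
}

# Mantegna's algorithm for symmetric Levy-stable step lengths
levy_steps <- function(n, beta) {
  sigma_u <- (gamma(1 + beta) * sin(pi * beta / 2) /
                (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
  rnorm(n, sd = sigma_u) / abs(rnorm(n))^(1 / beta)
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Minimize an objective with the walrus optimizer
#'
#' Box-constrained global minimization. Each iteration draws a danger
#' signal `A * R` with `A = 2 * gamma`, `gamma = 1 - l/I` decaying from 1
#' to 0, and `R` uniform on (-1, 1), plus a safety signal uniform on
#' (0, 1). When `|danger| >= 1` the herd migrates: every individual steps
#' by `(X_m - X_n) * beta * r^2` along the difference of two random herd
#' members, with a sigmoidal step-control factor `beta`. Otherwise the
#' reproduction updates apply: females move deterministically toward a
#' blend of a paired male and the global best (weights `gamma` and
#' `1 - gamma`); males scout by a bounded random walk attracted to the
#' global best and to a random partner; juveniles flee toward a
#' Levy-perturbed safety position when the safety signal is below 0.5.
#' Positions are clamped to the box after every update; the best-so-far
#' solution is kept elitistically, so the fitness history never increases.
#'
#' @param objective Function mapping a position vector to a finite scalar;
#'   non-finite returns are treated as `+Inf`.
#' @param config A [wo_config()]; its `bounds` must be set.
#' @return An object of class `wo_result`: `best_position`,
#'   `best_fitness`, `history` (best-so-far fitness per iteration, length
#'   `max_iter`) and `evaluations` (objective call count,
#'   `pop_size * (max_iter + 1)`).
#' @examples
#' sphere <- function(x) sum(x^2)
#' cfg <- wo_config(pop_size = 20, max_iter = 50,
#'                  bounds = rbind(c(-5, -5), c(5, 5)), seed = 1)
#' wo_minimize(sphere, cfg)$best_fitness
#' @export
wo_minimize <- function(objective, config) {
  stopifnot(inherits(config, "wo_config"))
  b <- check_bounds(config$bounds)
  d <- ncol(b)
  lower <- b[1L, ]; upper <- b[2L, ]
  N <- config$pop_size
  I <- config$max_iter
  int_dims <- if (is.null(config$integer_dims)) rep(FALSE, d)
              else rep_len(as.logical(config$integer_dims), d)

  eval_count <- 0L
  fit1 <- function(pos) {
    eval_count <<- eval_count + 1L
    p <- pos
    p[int_dims] <- round(p[int_dims])
    v <- objective(p)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) Inf else v
  }

  with_seed(config$seed, {
    X <- matrix(runif(N * d, min = rep(lower, each = N),
                      max = rep(upper, each = N)), N, d)
    fit <- apply(X, 1L, fit1)
    if (all(!is.finite(fit)))
      stop("objective returned non-finite values for the entire population")
    best_i <- which.min(fit)
    best_x <- X[best_i, ]
    best_f <- fit[best_i]

    n_male <- max(1L, round(config$role_fractions[1L] * N))
    n_female <- max(1L, round(config$role_fractions[2L] * N))
    if (n_male + n_female >= N) n_female <- N - n_male - 1L
    n_juv <- N - n_male - n_female
    males <- seq_len(n_male)
    females <- n_male + seq_len(n_female)
    juveniles <- if (n_juv > 0L) n_male + n_female + seq_len(n_juv)
                 else integer(0)

    history <- numeric(I)
    for (l in seq_len(I)) {
      g <- 1 - l / I
      danger <- (2 * g) * (2 * runif(1) - 1)
      safety <- runif(1)
      Xold <- X
      if (abs(danger) >= 1) {
        beta <- 1 - 1 / (1 + exp(-10 * (l - 0.5 * I) / I))
        for (i in seq_len(N)) {
          mn <- sample.int(N, 2L)
          X[i, ] <- Xold[i, ] +
            (Xold[mn[1L], ] - Xold[mn[2L], ]) * beta * runif(d)^2
        }
      } else {
        for (i in males) {
          partner <- sample.int(N, 1L)
          X[i, ] <- Xold[i, ] + g * runif(d) * (best_x - Xold[i, ]) +
            (1 - g) * runif(d) * (Xold[partner, ] - Xold[i, ])
        }
        for (j in seq_along(females)) {
          i <- females[j]
          m <- males[1L + (j - 1L) %% n_male]
          X[i, ] <- Xold[i, ] + g * (Xold[m, ] - Xold[i, ]) +
            (1 - g) * (best_x - Xold[i, ])
        }
        for (i in juveniles) {
          if (safety < 0.5) {
            O <- best_x + Xold[i, ] * levy_steps(d, config$levy_exponent)
            X[i, ] <- (O - Xold[i, ]) * runif(1)
          } else {
            X[i, ] <- Xold[i, ] + runif(d) * (best_x - Xold[i, ])
          }
        }
      }
      X <- pmin(pmax(X, rep(lower, each = N)), rep(upper, each = N))
      fit <- apply(X, 1L, fit1)
      i <- which.min(fit)
      if (fit[i] < best_f) {
        best_f <- fit[i]
        best_x <- X[i, ]
      }
      history[l] <- best_f
    }

    best_x[int_dims] <- round(best_x[int_dims])
    structure(list(best_position = best_x, best_fitness = best_f,
                   history = history, evaluations = eval_count),
              class = "wo_result")
  })
}

#' @export
print.wo_result <- function(x, ...) {
  cat(sprintf("<wo_result> best fitness %.6g at (%s) after %d evaluations\n",
              x$best_fitness,
              paste(sprintf("%.4g", x$best_position), collapse = ", "),
              x$evaluations))
  invisible(x)
}
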