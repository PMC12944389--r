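# Hyperparameter search: the walrus optimizer explores (K, alpha); every
# fitness evaluation runs a full VMD of the signal and scores it by the
# energy-gated minimum mode envelope entropy.

#' Optimize VMD hyperparameters for a signal
#'
#' Runs the walrus optimizer over the (K, alpha) box; each candidate is
#' evaluated by decomposing the signal with those parameters and scoring
#' the decomposition with [mmee_fitness()]. `K` is searched continuously
#' but rounded to the nearest integer at evaluation; `alpha` is quantized
#' to a resolution of 1 at evaluation, which makes fitness caching exact
#' (the optimizer frequently revisits near-identical positions).
#'
#' The search runs on the full record including the rest prefix, so the
#' resulting modes cover the resting span needed for threshold
#' calibration downstream.
#'
#' @param signal A preprocessed [semg_signal()].
#' @param wo A [wo_config()]; its `bounds` field is ignored in favor of
#'   `k_bounds` / `alpha_bounds`.
#' @param k_bounds Integer search range for the mode count (default 2-15).
#' @param alpha_bounds Search range for the bandwidth penalty (default
#'   500-2000).
#' @param tau,tol,max_iter VMD solver controls, see [vmd_params()].
#' @param energy_gate Passed to [mmee_fitness()].
#' @return List with `K_opt`, `alpha_opt`, `result` (the [wo_minimize()]
#'   output), `cache_hits` and `unique_evaluations`.
#' @export
optimize_vmd_params <- function(signal, wo = wo_config(),
                                k_bounds = c(2, 15),
                                alpha_bounds = c(500, 2000),
                                tau = 0, tol = 1e-6, max_iter = 500,
                                energy_gate = 0.01) {
  stopifnot(inherits(signal, "semg_signal"))
  if (length(signal$samples) < 2 * max(k_bounds))
    stop("signal too short for the largest K in `k_bounds`")
  wo$bounds <- rbind(c(k_bounds[1L], alpha_bounds[1L]),
                     c(k_bounds[2L], alpha_bounds[2L]))
  wo$integer_dims <- c(TRUE, FALSE)

  cache <- new.env(parent = emptyenv())
  hits <- 0L
  objective <- function(pos) {
    K <- as.integer(round(pos[1L]))
    a <- round(pos[2L])  # quantize alpha for exact cache keys
    key <- paste0(K, "_", a)
    if (!is.null(cache[[key]])) {
      hits <<- hits + 1L
      return(cache[[key]])
    }
    ms <- vmd_decompose(signal, vmd_params(K = K, alpha = a, tau = tau,
                                           tol = tol, max_iter = max_iter))
    v <- mmee_fitness(ms, energy_gate = energy_gate)
    cache[[key]] <- v
    v
  }

  res <- wo_minimize(objective, wo)
  list(K_opt = as.integer(round(res$best_position[1L])),
       alpha_opt = round(res$best_position[2L]),
       result = res,
       cache_hits = hits,
       unique_evaluations = res$evaluations - hits)
}

#' Final decomposition at the optimized parameters
#'
#' Thin wrapper over [vmd_decompose()] at the parameters returned by
#' [optimize_vmd_params()]; the inner solver is deterministic, so
#' re-running with the same inputs reproduces the decomposition exactly.
#'
#' @param signal A [semg_signal()].
#' @param K_opt,alpha_opt Optimized mode count and penalty.
#' @inheritParams optimize_vmd_params
#' @return A `vmd_modeset`.
#' @export
decompose_with_optimal <- function(signal, K_opt, alpha_opt,
                                   tau = 0, tol = 1e-6, max_iter = 500) {
  vmd_decompose(signal, vmd_params(K = K_opt, alpha = alpha_opt, tau = tau,
                                   tol = tol, max_iter = max_iter))
}
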