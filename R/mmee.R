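# Minimum mode envelope entropy: the model-selection fitness for the VMD
# hyperparameter search. Structured burst activity concentrates its Hilbert
# envelope in time (low Shannon entropy of the normalized envelope), while
# noise-dominated modes have a temporally diffuse envelope (high entropy).
# A well-parameterized decomposition therefore produces at least one
# low-entropy mode, and the fitness is the minimum entropy over modes that
# carry a non-negligible share of the energy.

# analytic signal via the frequency-domain Hilbert filter
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1
    h[n / 2 + 1L] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Hilbert envelope of a series
#'
#' Magnitude of the analytic signal, i.e. the instantaneous amplitude.
#'
#' @param mode Numeric series of length >= 4, finite.
#' @return Non-negative numeric vector of the same length.
#' @export
envelope <- function(mode) {
  mode <- as.numeric(mode)
  if (length(mode) < 4L) stop("`mode` must have length >= 4")
  if (!all(is.finite(mode))) stop("`mode` must be finite")
  Mod(analytic_signal(mode))
}

#' Envelope entropy of a mode
#'
#' Shannon entropy (bits) of the Hilbert envelope normalized to a
#' probability distribution over time: `E = -sum(p * log2(p))` with
#' `p_j = a_j / sum(a)`. Bounded by `[0, log2(N)]`; a constant envelope
#' attains the upper bound, a single-sample point mass the lower.
#'
#' @param mode Numeric series (the envelope is computed internally), or a
#'   ready-made non-negative envelope when `is_envelope = TRUE`.
#' @param is_envelope Set `TRUE` to treat `mode` as the envelope itself
#'   and skip the Hilbert transform.
#' @return Entropy in bits.
#' @export
envelope_entropy <- function(mode, is_envelope = FALSE) {
  a <- if (is_envelope) {
    a <- as.numeric(mode)
    if (any(a < 0) || !all(is.finite(a))) stop("envelope must be >= 0")
    a
  } else {
    envelope(mode)
  }
  s <- sum(a)
  if (s <= 0) {
    warning("zero-mass envelope; returning maximal entropy log2(N)")
    return(log2(length(a)))
  }
  p <- a / s
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Minimum mode envelope entropy fitness
#'
#' The minimum envelope entropy over the modes of a decomposition,
#' restricted to modes whose energy is at least `energy_gate` times the
#' total mode energy. The gate prevents near-empty modes (whose envelopes
#' can be spuriously concentrated) from dominating the minimum; if no mode
#' passes the gate, the minimum is taken over all modes.
#'
#' @param modeset A `vmd_modeset` from [vmd_decompose()].
#' @param energy_gate Energy fraction below which a mode is excluded from
#'   the minimum (default 1\%).
#' @return The fitness value (bits); smaller indicates a decomposition
#'   with a more structured, less noise-like best mode.
#' @export
mmee_fitness <- function(modeset, energy_gate = 0.01) {
  stopifnot(inherits(modeset, "vmd_modeset"), ncol(modeset$modes) >= 1L)
  energy <- colSums(modeset$modes^2)
  total <- sum(energy)
  keep <- if (total > 0) energy >= energy_gate * total
          else rep(TRUE, length(energy))
  if (!any(keep)) keep <- rep(TRUE, length(energy))
  ent <- apply(modeset$modes[, keep, drop = FALSE], 2L, envelope_entropy)
  min(ent)
}
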