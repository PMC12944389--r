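#' VMD decomposition controls
#'
#' Bundles the tunable parameters of variational mode decomposition.
#'
#' @param K Number of modes (integer >= 1). Too small a `K` mixes distinct
#'   components into one mode; too large a `K` splits components and
#'   produces spurious modes.
#' @param alpha Bandwidth penalty (> 0). Larger values yield narrower
#'   modes.
#' @param tau Dual-ascent step ("noise tolerance"). `tau = 0` relaxes the
#'   exact-reconstruction constraint, the usual choice when the input is
#'   noisy; `tau > 0` enforces reconstruction progressively.
#' @param tol Convergence tolerance on the summed relative change of the
#'   mode spectra between sweeps.
#' @param max_iter Iteration cap for non-converging settings.
#' @return An object of class `vmd_params`.
#' @export
vmd_params <- function(K, alpha, tau = 0, tol = 1e-6, max_iter = 500) {
  K <- as.integer(round(K))
  if (is.na(K) || K < 1L) stop("`K` must be an integer >= 1")
  if (!is.finite(alpha) || alpha <= 0) stop("`alpha` must be > 0")
  if (!is.finite(tau) || tau < 0) stop("`tau` must be >= 0")
  if (!is.finite(tol) || tol <= 0) stop("`tol` must be > 0")
  max_iter <- as.integer(max_iter)
  if (is.na(max_iter) || max_iter < 1L) stop("`max_iter` must be >= 1")
  structure(list(K = K, alpha = as.numeric(alpha), tau = as.numeric(tau),
                 tol = as.numeric(tol), max_iter = max_iter),
            class = "vmd_params")
}

fftshift_even <- function(x) {
  n <- length(x)
  c(x[(n / 2 + 1):n], x[1:(n / 2)])
}

#' Variational mode decomposition
#'
#' Decomposes a signal into `K` band-limited modes with adaptive center
#' frequencies by solving the VMD variational problem with ADMM in the
#' frequency domain. Each mode is a Wiener-type refit around its current
#' center frequency against the residual of the other modes; center
#' frequencies move to the power-weighted mean frequency of their mode.
#'
#' Boundaries are handled by mirror-extending the input by half its length
#' on each side before the FFT and cropping after inversion. Center
#' frequencies are initialized uniformly over `(0, fs/4]`, which makes the
#' solver fully deterministic. Updates act on the one-sided spectrum;
#' Hermitian symmetry is restored on inversion so the modes are real.
#'
#' @param signal A [semg_signal()] (or numeric vector, in which case `fs`
#'   must be supplied).
#' @param params A [vmd_params()] object.
#' @param fs Sampling rate, only needed when `signal` is a bare vector.
#' @return An object of class `vmd_modeset`: list with `modes` (an
#'   n-by-K matrix, columns sorted by ascending center frequency), `omega`
#'   (center frequencies in Hz), `fs`, `n_iter`, `converged`, and
#'   `residual_history` (relative reconstruction residual per iteration).
#' @examples
#' fs <- 1500
#' t <- (1:4500) / fs
#' s <- semg_signal(sin(2 * pi * 50 * t) + sin(2 * pi * 200 * t), fs)
#' m <- vmd_decompose(s, vmd_params(K = 2, alpha = 2000))
#' round(m$omega)
#' @export
vmd_decompose <- function(signal, params, fs = NULL) {
  if (inherits(signal, "semg_signal")) {
    x <- signal$samples
    fs <- signal$fs
  } else {
    x <- as.numeric(signal)
    if (is.null(fs)) stop("`fs` required when `signal` is a bare vector")
  }
  stopifnot(inherits(params, "vmd_params"))
  if (!all(is.finite(x))) stop("input contains non-finite values")
  n <- length(x)
  K <- params$K
  if (n < 2L * K) stop("signal too short: need length >= 2 * K")

  # mirror extension by half the length on each side -> even total length
  nL <- floor(n / 2)
  nR <- n - nL
  xm <- c(rev(x[1:nL]), x, rev(x[(n - nR + 1):n]))
  TT <- length(xm)  # 2 n, always even
  freqs <- ((0:(TT - 1)) - TT / 2) / TT
  fh <- fftshift_even(stats::fft(xm))
  hp <- (TT / 2 + 1):TT  # non-negative frequencies incl. DC
  omega0 <- 0.25 * (1:K) / K

  res <- vmd_admm_cpp(fh[hp], freqs[hp], K, params$alpha, params$tau,
                      params$tol, params$max_iter, omega0)

  Tp <- length(hp)
  modes <- matrix(0, n, K)
  for (k in 1:K) {
    uh <- complex(real = numeric(TT))
    uh[hp] <- res$u_plus[, k]
    uh[(TT / 2):2] <- Conj(res$u_plus[2:Tp, k])
    uh[1L] <- Conj(uh[TT])
    ut <- Re(stats::fft(fftshift_even(uh), inverse = TRUE)) / TT
    modes[, k] <- ut[(nL + 1):(nL + n)]
  }
  omega_hz <- pmin(pmax(res$omega * fs, 0), fs / 2)
  ord <- order(omega_hz)
  structure(list(modes = modes[, ord, drop = FALSE],
                 omega = omega_hz[ord], fs = fs,
                 n_iter = res$n_iter, converged = res$converged,
                 residual_history = res$residual_history),
            class = "vmd_modeset")
}

#' @export
print.vmd_modeset <- function(x, ...) {
  cat(sprintf("<vmd_modeset> K = %d, %d samples @ %g Hz, %d iterations%s\n",
              ncol(x$modes), nrow(x$modes), x$fs, x$n_iter,
              if (x$converged) "" else " (not converged)"))
  cat("  center frequencies (Hz):", paste(sprintf("%.1f", x$omega),
                                          collapse = ", "), "\n")
  invisible(x)
}

#' Sum the modes of a decomposition
#'
#' The pointwise sum of all modes, i.e. the decomposition's reconstruction
#' of the input under the constraint that the modes add up to the signal.
#'
#' @param modeset A `vmd_modeset` from [vmd_decompose()].
#' @return Numeric vector of the input length.
#' @export
vmd_reconstruct <- function(modeset) {
  stopifnot(inherits(modeset, "vmd_modeset"), ncol(modeset$modes) >= 1L)
  rowSums(modeset$modes)
}
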