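# Physiological-band screening: modes whose mean instantaneous frequency
# falls outside the band carried by surface EMG are discarded before
# thresholding and reconstruction.

#' Mean instantaneous frequency of a mode
#'
#' The instantaneous frequency is the derivative of the unwrapped phase of
#' the analytic signal; its mean (in Hz) locates a narrowband mode on the
#' frequency axis. The first and last `trim` fraction of samples are
#' excluded from the mean because the Hilbert transform is unreliable at
#' the edges. The result is clipped to `[0, fs/2]`.
#'
#' @param mode Numeric series, length >= 16.
#' @param fs Sampling rate in Hz.
#' @param trim Edge fraction excluded at each end (default 5\%).
#' @return Mean instantaneous frequency in Hz.
#' @export
mean_instfreq <- function(mode, fs, trim = 0.05) {
  mode <- as.numeric(mode)
  if (length(mode) < 16L) stop("`mode` must have length >= 16")
  if (all(mode == 0)) {
    warning("all-zero mode; mean instantaneous frequency defined as 0 Hz")
    return(0)
  }
  z <- analytic_signal(mode)
  dphi <- diff(Arg(z))
  dphi <- (dphi + pi) %% (2 * pi) - pi  # unwrap increments to (-pi, pi]
  n <- length(dphi)
  lo <- max(1L, floor(trim * n) + 1L)
  hi <- min(n, n - floor(trim * n))
  f <- mean(dphi[lo:hi]) * fs / (2 * pi)
  min(max(f, 0), fs / 2)
}

#' Select modes inside the physiological band
#'
#' Returns the indices of modes whose mean instantaneous frequency lies
#' inside `band`. The default band equals the preprocessing passband
#' (10-500 Hz), the range carrying surface-EMG energy. An empty selection
#' is returned as `integer(0)`; callers are expected to fall back to all
#' modes rather than silently deleting the signal (the pipeline does).
#'
#' @param modeset A `vmd_modeset`.
#' @param band Numeric `c(low, high)` in Hz.
#' @return Integer vector of selected mode indices (possibly empty),
#'   in mode order.
#' @export
select_modes <- function(modeset, band = c(10, 500)) {
  stopifnot(inherits(modeset, "vmd_modeset"), length(band) == 2L,
            band[1L] < band[2L])
  mif <- apply(modeset$modes, 2L, mean_instfreq, fs = modeset$fs)
  which(mif >= band[1L] & mif <= band[2L])
}
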