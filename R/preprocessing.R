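# Front-end filtering: Butterworth band-pass to the sEMG band plus a narrow
# notch at the power-line frequency. Both filters are applied zero-phase
# (forward-backward), which squares the magnitude response and cancels the
# phase, so burst timing is preserved for the interval-thresholding stage.

# Odd-symmetric (point-reflected) padding suppresses filter startup
# transients; pad length approximates one settling length of the filter.
filtfilt_reflect <- function(b, a, x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  if (pad > 0L) {
    pre <- 2 * x[1L] - x[(pad + 1L):2L]
    post <- 2 * x[n] - x[(n - 1L):(n - pad)]
    y <- signal::filtfilt(b, a, c(pre, x, post))
    y[(pad + 1L):(pad + n)]
  } else {
    signal::filtfilt(b, a, x)
  }
}

#' Band-pass filter a signal
#'
#' Zero-phase Butterworth band-pass (default fourth order, 10-500 Hz), the
#' standard sEMG front end: it removes baseline drift and motion-artifact
#' energy below the band and out-of-band high-frequency noise above it.
#'
#' @param signal A [semg_signal()].
#' @param low,high Band edges in Hz; `0 < low < high < fs/2`.
#' @param order Butterworth order of the one-way filter (the effective
#'   order doubles under forward-backward application).
#' @return A [semg_signal()] of the same length, fs and rest span.
#' @export
bandpass <- function(signal, low = 10, high = 500, order = 4) {
  stopifnot(inherits(signal, "semg_signal"))
  nyq <- signal$fs / 2
  if (!(low > 0 && low < high)) stop("need 0 < low < high")
  if (high >= nyq) stop("invalid band: `high` must be below fs/2 = ", nyq)
  flt <- signal::butter(order, c(low, high) / nyq, type = "pass")
  pad <- max(256L, as.integer(round(3 * signal$fs / low)))
  y <- filtfilt_reflect(flt$b, flt$a, signal$samples, pad)
  semg_signal(y, fs = signal$fs, rest_span = signal$rest_span)
}

#' Notch filter a signal
#'
#' Zero-phase second-order Butterworth band-stop centered at the power-line
#' frequency, suppressing power-line interference. The stop band has width
#' `freq / q`.
#'
#' @param signal A [semg_signal()].
#' @param freq Notch center frequency in Hz (50 for European mains).
#' @param q Quality factor; larger values narrow the notch.
#' @return A [semg_signal()] of the same length, fs and rest span.
#' @export
notch <- function(signal, freq = 50, q = 30) {
  stopifnot(inherits(signal, "semg_signal"))
  nyq <- signal$fs / 2
  if (!(freq > 0 && freq < nyq))
    stop("invalid band: `freq` must lie in (0, fs/2)")
  bw <- freq / q
  flt <- signal::butter(2, c(freq - bw / 2, freq + bw / 2) / nyq,
                        type = "stop")
  pad <- max(256L, as.integer(round(3 * q * signal$fs / freq)))
  y <- filtfilt_reflect(flt$b, flt$a, signal$samples, pad)
  semg_signal(y, fs = signal$fs, rest_span = signal$rest_span)
}

#' Standard sEMG preprocessing chain
#'
#' Band-pass (10-500 Hz, fourth order) followed by a 50 Hz notch, both
#' zero-phase. This is the front end applied before decomposition.
#'
#' @param signal A [semg_signal()].
#' @inheritParams bandpass
#' @inheritParams notch
#' @param notch_freq,notch_q Notch parameters passed to [notch()].
#' @return The filtered [semg_signal()].
#' @export
preprocess <- function(signal, low = 10, high = 500, order = 4,
                       notch_freq = 50, notch_q = 30) {
  notch(bandpass(signal, low = low, high = high, order = order),
        freq = notch_freq, q = notch_q)
}
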