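# Shared fixture builders for the suite. Everything is generated in code.

fs_default <- 1500

tone <- function(freq, seconds, fs = fs_default, amp = 1) {
  amp * sin(2 * pi * freq * (1:round(seconds * fs)) / fs)
}

two_tone_signal <- function(seconds = 3, fs = fs_default) {
  semg_signal(tone(50, seconds, fs) + tone(200, seconds, fs), fs)
}

# wrap plain series into a modeset (for selection/thresholding tests)
make_modeset <- function(modes, fs = fs_default) {
  m <- as.matrix(modes)
  structure(list(modes = m, omega = rep(NA_real_, ncol(m)), fs = fs,
                 n_iter = 0L, converged = TRUE,
                 residual_history = numeric(0)),
            class = "vmd_modeset")
}

# fraction of a series' periodogram energy inside [lo, hi] Hz
band_energy_fraction <- function(x, fs, lo, hi) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  half <- p[seq_len(n %/% 2 + 1)]
  f <- (seq_along(half) - 1) * fs / n
  sum(half[f >= lo & f <= hi]) / sum(half)
}

# energy of a series inside a +/- width Hz band around f0
band_energy <- function(x, fs, f0, width) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  half <- p[seq_len(n %/% 2 + 1)]
  f <- (seq_along(half) - 1) * fs / n
  sum(half[abs(f - f0) <= width])
}

fft_peak_hz <- function(x, fs) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  half <- p[seq_len(n %/% 2 + 1)]
  (which.max(half) - 1) * fs / n
}
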