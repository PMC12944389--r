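#' Sampled-signal container
#'
#' A `semg_signal` holds a uniformly sampled single-channel amplitude series
#' together with its sampling rate and, optionally, a resting-segment span.
#' The resting span marks samples recorded while the muscle was relaxed; it
#' is the calibration window for rest-based noise estimation (see
#' [estimate_sigma()]).
#'
#' Sample indices follow a single convention throughout the package:
#' 0-based, half-open `[start, end)`. A span `c(0, 7500)` therefore covers
#' the first 7500 samples.
#'
#' @param samples Numeric vector of amplitudes (arbitrary units, typically
#'   mV). Must be finite and of length at least 2.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param rest_span Optional integer vector `c(start, end)`, a 0-based
#'   half-open sample-index interval marking the resting segment, with
#'   `0 <= start < end <= length(samples)`.
#' @return An object of class `semg_signal`: a list with elements
#'   `samples`, `fs` and `rest_span` (the latter `NULL` when absent).
#' @examples
#' s <- semg_signal(sin(2 * pi * 50 * (0:999) / 1500), fs = 1500)
#' s
#' @export
semg_signal <- function(samples, fs, rest_span = NULL) {
  if (!is.numeric(samples)) stop("`samples` must be numeric")
  samples <- as.numeric(samples)
  if (length(samples) < 2L) stop("`samples` must contain at least 2 values")
  if (!all(is.finite(samples))) stop("`samples` must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a positive scalar (Hz)")
  if (!is.null(rest_span)) {
    rest_span <- as.integer(round(rest_span))
    if (length(rest_span) != 2L || anyNA(rest_span))
      stop("`rest_span` must be c(start, end)")
    if (rest_span[1L] < 0L || rest_span[1L] >= rest_span[2L] ||
        rest_span[2L] > length(samples))
      stop("`rest_span` must satisfy 0 <= start < end <= length(samples)")
  }
  structure(list(samples = samples, fs = as.numeric(fs),
                 rest_span = rest_span),
            class = "semg_signal")
}

#' @export
print.semg_signal <- function(x, ...) {
  cat(sprintf("<semg_signal> %d samples @ %g Hz (%.3f s)\n",
              length(x$samples), x$fs, length(x$samples) / x$fs))
  if (!is.null(x$rest_span))
    cat(sprintf("  rest span: [%d, %d) (%.3f s)\n", x$rest_span[1L],
                x$rest_span[2L], diff(x$rest_span) / x$fs))
  invisible(x)
}

# 1-based R indices of the resting samples
rest_indices <- function(x) {
  stopifnot(inherits(x, "semg_signal"), !is.null(x$rest_span))
  (x$rest_span[1L] + 1L):x$rest_span[2L]
}

sidecar_path <- function(path) paste0(sub("\\.[^./\\\\]*$", "", path), ".json")

#' Read a signal from a one-column text file
#'
#' Reads a single numeric column (optionally preceded by one header line)
#' and attaches the sampling rate and resting span. If a JSON sidecar file
#' with the same stem (e.g. `rec.json` next to `rec.csv`) exists it supplies
#' `fs` and `rest_span`; explicit arguments override the sidecar.
#'
#' @param path Path to the sample file.
#' @param fs Sampling rate in Hz. May be omitted when a sidecar provides it.
#' @param rest_seconds Optional duration (s) of a resting prefix; sets
#'   `rest_span = [0, round(rest_seconds * fs))`.
#' @return A [semg_signal()].
#' @seealso [write_signal()]
#' @export
read_signal <- function(path, fs = NULL, rest_seconds = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty signal file: ", path)

  rest_span <- NULL
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (is.null(fs) && !is.null(meta$fs)) fs <- meta$fs
    if (!is.null(meta$rest_span)) rest_span <- as.integer(meta$rest_span)
  }
  if (is.null(fs)) stop("`fs` not given and no sidecar provides it")

  first <- suppressWarnings(as.numeric(lines[1L]))
  if (is.na(first) && !identical(toupper(lines[1L]), "NA"))
    lines <- lines[-1L]  # header line
  vals <- suppressWarnings(as.numeric(lines))
  if (anyNA(vals) || !all(is.finite(vals)))
    stop("non-numeric or non-finite rows in ", path)

  if (!is.null(rest_seconds)) {
    n_rest <- round(rest_seconds * fs)
    if (n_rest < 1 || n_rest >= length(vals))
      stop("invalid rest duration: rest_seconds * fs must lie in [1, length)")
    rest_span <- c(0L, as.integer(n_rest))
  }
  semg_signal(vals, fs = fs, rest_span = rest_span)
}

#' Write a signal to a one-column text file plus JSON sidecar
#'
#' Samples are written as one numeric column (header `amplitude`) with full
#' double precision, so that a write/read round trip is lossless to within
#' 1e-9 relative error. Sampling rate and resting span go into a JSON
#' sidecar with the same stem.
#'
#' @param signal A [semg_signal()].
#' @param path Output path for the sample column.
#' @return Invisibly, `path`.
#' @export
write_signal <- function(signal, path) {
  stopifnot(inherits(signal, "semg_signal"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("amplitude", sprintf("%.17g", signal$samples)), con)
  meta <- list(fs = signal$fs)
  if (!is.null(signal$rest_span)) meta$rest_span <- signal$rest_span
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
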