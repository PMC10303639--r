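#' Zero-phase Butterworth bandpass filter
#'
#' Suppresses baseline wander and high-frequency interference with a
#' Butterworth bandpass (default 2--30 Hz, order 6) applied forward and
#' backward (`signal::filtfilt`), so the effective magnitude response is the
#' squared one-pass response and the phase response is zero. Zero-phase
#' application matters here because downstream QRS boundaries are timing
#' landmarks: a causal filter would shift them.
#'
#' @param rec An [ecg_record()].
#' @param low,high Band edges in Hz; must satisfy `0 < low < high < fs/2`.
#' @param order Bandpass filter order (even; the underlying lowpass
#'   prototype has order `order/2`).
#' @return A filtered [ecg_record()] of the same length.
#' @examples
#' rec <- ecg_record(rnorm(5000), fs = 500)
#' filt <- bandpass_filter(rec)
#' @export
bandpass_filter <- function(rec, low = 2, high = 30, order = 6) {
  stopifnot(inherits(rec, "ecg_record"))
  if (!(low > 0 && high > low && high < rec$fs / 2))
    stop("band edges must satisfy 0 < low < high < fs/2")
  if (order < 2 || order %% 2 != 0) stop("'order' must be a positive even number")
  bf <- signal::butter(order / 2, c(low, high) / (rec$fs / 2), type = "pass")
  # filtfilt pads by ~3x the filter length; require enough samples
  if (length(rec$samples) <= 3 * (length(bf$b) + 1))
    stop("record too short for the filter warm-up length")
  out <- rec
  out$samples <- as.numeric(signal::filtfilt(bf, rec$samples))
  out
}

#' Designed magnitude response of the bandpass filter
#'
#' Returns the two-pass (forward-backward) magnitude response `|H(f)|^2` of
#' the filter designed by [bandpass_filter()], evaluated at the requested
#' frequencies. Mainly used to verify filtering behaviour.
#'
#' @param f Frequencies in Hz.
#' @param fs Sampling rate in Hz.
#' @inheritParams bandpass_filter
#' @return Numeric vector of magnitude ratios (output/input amplitude).
#' @export
bandpass_response <- function(f, fs, low = 2, high = 30, order = 6) {
  bf <- signal::butter(order / 2, c(low, high) / (fs / 2), type = "pass")
  w <- 2 * pi * f / fs
  vapply(w, function(wi) {
    num <- sum(bf$b * exp(-1i * wi * (seq_along(bf$b) - 1)))
    den <- sum(bf$a * exp(-1i * wi * (seq_along(bf$a) - 1)))
    Mod(num / den)^2
  }, numeric(1))
}

#' Resample a sequence to a target length by linear interpolation
#'
#' Evaluates the piecewise-linear interpolant of `seq` on a uniform grid of
#' `target_len` points spanning the full sequence; the first and last
#' samples are preserved exactly. Used to bring R-to-R beat segments to a
#' common length before clustering and time warping.
#'
#' @param seq Numeric vector of length >= 2.
#' @param target_len Target length (>= 2).
#' @return Numeric vector of length `target_len`.
#' @examples
#' resample_to_length(c(0, 1), 3) # 0, 0.5, 1
#' @export
resample_to_length <- function(seq, target_len) {
  n <- length(seq)
  if (n < 2L) stop("'seq' must have at least 2 samples")
  if (target_len < 2L) stop("'target_len' must be at least 2")
  if (target_len == n) return(as.numeric(seq))
  stats::approx(x = seq_len(n), y = seq,
                xout = seq(1, n, length.out = target_len))$y
}

#' Min-max scale a sequence to [0, 1]
#'
#' Computes `(x - min) / (max - min)`. A constant (flat-line) input cannot
#' be scaled; it is returned as all zeros with attribute `degenerate = TRUE`
#' so that callers can exclude it from clustering and warping (flat segments
#' arise when artifacts saturate the front end).
#'
#' @param seq Numeric vector of length >= 2.
#' @return Numeric vector in `[0, 1]` with a logical `degenerate` attribute.
#' @examples
#' minmax_scale(c(0, 5, 10))
#' @export
minmax_scale <- function(seq) {
  if (length(seq) < 2L) stop("'seq' must have at least 2 samples")
  rng <- range(seq)
  if (rng[1] == rng[2]) {
    out <- rep(0, length(seq))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- (seq - rng[1]) / (rng[2] - rng[1])
  attr(out, "degenerate") <- FALSE
  out
}
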