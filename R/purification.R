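#' Normalize raw beat distortions
#'
#' Divides raw terminal path distances by a reference maximum — the
#' largest raw distortion observed on the subject's training session —
#' and clips to `[0, 1]`, so the triangle threshold learned on training
#' transfers directly to the testing session. Non-finite raw values
#' (degenerate beats) map to 1.
#'
#' @param raw Nonnegative raw distortions.
#' @param reference_max Positive training-session maximum.
#' @return Numeric vector in `[0, 1]`.
#' @export
normalize_distortions <- function(raw, reference_max) {
  if (!is.numeric(reference_max) || length(reference_max) != 1L ||
      !is.finite(reference_max) || reference_max <= 0)
    stop("'reference_max' must be a single positive number")
  out <- raw / reference_max
  out[!is.finite(out)] <- 1
  pmin(pmax(out, 0), 1)
}

#' Learn the distortion threshold by the histogram triangle method
#'
#' Builds an equal-width histogram of the normalized distortions and draws
#' the hypotenuse from the maximum-count bin to the rightmost nonempty
#' bin (in bin-index / count coordinates). The threshold is the centre of
#' the bin, between those two, whose point `(b, h(b))` has the maximum
#' perpendicular distance to that line — the natural transition between
#' the concentrated low-distortion mass of clean beats and the long right
#' tail of distorted ones. The histogram is expected (not required) to be
#' left-skewed.
#'
#' @param values Normalized distortions.
#' @param nbins Number of histogram bins.
#' @return An object of class `mqrs_hist`: list with `breaks`, `counts`,
#'   `mids`, `b_max`, `b_right`, `distances` (one per bin in the searched
#'   range), and the threshold `tau`.
#' @export
triangle_threshold <- function(values, nbins = 50) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) stop("need at least 2 finite distortion values")
  rng <- range(values)
  if (rng[1] == rng[2]) stop("all distortion values identical; no threshold")
  breaks <- seq(rng[1], rng[2], length.out = nbins + 1L)
  counts <- graphics::hist(values, breaks = breaks, plot = FALSE)$counts
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  b_max <- which.max(counts)
  b_right <- max(which(counts > 0))
  if (b_right <= b_max)
    stop("histogram mass ends at its peak; no right tail to search")
  bs <- b_max:b_right
  x1 <- b_max; y1 <- counts[b_max]
  x2 <- b_right; y2 <- counts[b_right]
  distances <- abs((y2 - y1) * bs - (x2 - x1) * counts[bs] +
                     x2 * y1 - y2 * x1) / sqrt((y2 - y1)^2 + (x2 - x1)^2)
  tau_bin <- bs[which.max(distances)]
  structure(list(breaks = breaks, counts = counts, mids = mids,
                 b_max = b_max, b_right = b_right,
                 search_bins = bs, distances = distances,
                 tau = mids[tau_bin]),
            class = "mqrs_hist")
}

#' @export
print.mqrs_hist <- function(x, ...) {
  cat(sprintf("<mqrs_hist: %d bins, peak bin %d, rightmost bin %d, tau = %.4g>\n",
              length(x$counts), x$b_max, x$b_right, x$tau))
  invisible(x)
}

#' Smooth a distortion series by a trailing moving average
#'
#' Causal moving average of order `A`: each smoothed value is the mean of
#' the current and the `A - 1` preceding distortions (a shrinking window
#' at the start of the series, averaging the values available so far).
#' The smoothed series lets the quality index reject beats sitting inside
#' a bad neighbourhood even when their own distortion is low.
#'
#' @param pi Normalized distortion series.
#' @param A Moving-average order.
#' @return Numeric vector of the same length.
#' @export
smooth_distortions <- function(pi, A = 10) {
  if (A < 1L) stop("'A' must be >= 1")
  n <- length(pi)
  cs <- cumsum(pi)
  j <- seq_len(n)
  lo <- pmax(j - A, 0L)
  (cs - c(0, cs)[lo + 1L]) / (j - lo)
}

#' Per-beat signal quality index
#'
#' `SQI_j = 1` iff both the raw and the smoothed distortion are at or
#' below the learned threshold (boundary inclusive), else 0.
#'
#' @param pi Raw normalized distortions.
#' @param eta Smoothed distortions, same length.
#' @param tau Distortion threshold.
#' @return Integer vector of 0/1 flags.
#' @export
compute_sqi <- function(pi, eta, tau) {
  if (length(pi) != length(eta)) stop("'pi' and 'eta' must be the same length")
  as.integer(pi <= tau & eta <= tau)
}

#' Purify the located QRS set
#'
#' Retains only beats with `SQI = 1`. May legitimately return an empty
#' set under heavy artifacts; downstream minute averaging propagates the
#' resulting missingness rather than imputing.
#'
#' @param sqi Integer 0/1 flags, one per beat.
#' @return Integer indices of retained beats.
#' @export
purify <- function(sqi) {
  which(sqi == 1L)
}
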