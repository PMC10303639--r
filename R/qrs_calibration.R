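#' Assemble per-beat QRS durations across adjacent segments
#'
#' In R-to-R coordinates a segment holds one beat's QRS offset (near its
#' start) and the *next* beat's QRS onset (near its end), so the duration
#' of the beat centred on peak `R_j` stitches the onset located in segment
#' `j - 1` to the offset located in segment `j`. A duration is valid only
#' when both contributing segments have `SQI = 1`, neither is degenerate
#' or collapsed, and the value passes the sanity bound. Resampled
#' boundary indices are mapped back to record time continuously (no
#' rounding) to preserve sub-sample precision.
#'
#' @param segments Segment table from [segment_heartbeats()].
#' @param warps Data frame with one row per segment: `qrs_off`, `qrs_on`
#'   (1-based indices in resampled-beat coordinates), and logical
#'   `degenerate`/`collapsed` columns (missing columns treated as all
#'   `FALSE`).
#' @param sqi Integer 0/1 flags, one per segment.
#' @param fs Sampling rate (Hz).
#' @param resampled_len Common resampled beat length the warp indices
#'   refer to.
#' @param sanity_ms Upper sanity bound on a QRS duration (ms); durations
#'   outside `(0, sanity_ms]` are dropped and counted.
#' @return A data.frame with one row per interior peak: `beat` (peak
#'   number), `r_index` (record sample of the peak), `time_s`,
#'   `duration_ms`, and logical `valid`.
#' @export
beat_qrs_durations <- function(segments, warps, sqi, fs,
                               resampled_len = 256, sanity_ms = 300) {
  nseg <- nrow(segments)
  if (nseg < 2L) stop("need at least 2 segments to assemble a duration")
  if (nrow(warps) != nseg || length(sqi) != nseg)
    stop("'warps' and 'sqi' must have one entry per segment")
  degen <- if (!is.null(warps$degenerate)) warps$degenerate else rep(FALSE, nseg)
  coll <- if (!is.null(warps$collapsed)) warps$collapsed else rep(FALSE, nseg)
  usable <- sqi == 1L & !degen & !coll

  # beat j (j = 2..nseg, centred on the peak starting segment j):
  # onset from segment j-1, offset from segment j
  jj <- 2:nseg
  ratio_on <- (segments$length[jj - 1L] - 1) / (resampled_len - 1)
  ratio_off <- (segments$length[jj] - 1) / (resampled_len - 1)
  on_abs <- segments$start[jj - 1L] + (warps$qrs_on[jj - 1L] - 1) * ratio_on
  off_abs <- segments$start[jj] + (warps$qrs_off[jj] - 1) * ratio_off
  duration_ms <- (off_abs - on_abs) / fs * 1000
  valid <- usable[jj - 1L] & usable[jj] &
    is.finite(duration_ms) & duration_ms > 0 & duration_ms <= sanity_ms
  data.frame(beat = jj,
             r_index = segments$start[jj],
             time_s = (segments$start[jj] - 1) / fs,
             duration_ms = duration_ms,
             valid = valid)
}

#' Average beat durations over evaluation windows
#'
#' Arithmetic mean of valid per-beat durations within each (non-
#' overlapping) time window; a window containing no valid beat yields
#' `NA`, which is propagated — never imputed — through calibration and
#' evaluation.
#'
#' @param durations Data.frame from [beat_qrs_durations()].
#' @param spans Data.frame with `start_s` and `end_s` columns (half-open
#'   windows in seconds).
#' @return The `spans` data.frame with `estimate_ms` and `n_beats` added.
#' @export
minute_average <- function(durations, spans) {
  est <- numeric(nrow(spans))
  nb <- integer(nrow(spans))
  for (w in seq_len(nrow(spans))) {
    sel <- durations$valid & durations$time_s >= spans$start_s[w] &
      durations$time_s < spans$end_s[w]
    nb[w] <- sum(sel)
    est[w] <- if (nb[w] > 0L) mean(durations$duration_ms[sel]) else NA_real_
  }
  out <- spans
  out$estimate_ms <- est
  out$n_beats <- nb
  out
}

#' Learn the mobile-to-chest duration bias
#'
#' The calibration is a single additive offset per subject: the mean of
#' the chest-reference minute durations minus the mean of the mobile
#' minute estimates, over training minutes where both are present. No
#' higher-order calibration is attempted (it would overfit the handful of
#' training minutes and obscure how well the mobile estimates track the
#' chest lead).
#'
#' @param train_mobile Mobile minute estimates (ms), `NA` for missing.
#' @param train_chest Chest reference minute durations (ms), same length.
#' @return An object of class `mqrs_calibration` with `bias_ms` and
#'   `n_pairs`.
#' @export
fit_bias <- function(train_mobile, train_chest) {
  if (length(train_mobile) != length(train_chest))
    stop("mobile and chest minute series must be aligned")
  ok <- is.finite(train_mobile) & is.finite(train_chest)
  if (!any(ok)) stop("no paired non-missing training minutes")
  structure(list(bias_ms = mean(train_chest[ok]) - mean(train_mobile[ok]),
                 n_pairs = sum(ok)),
            class = "mqrs_calibration")
}

#' @export
print.mqrs_calibration <- function(x, ...) {
  cat(sprintf("<mqrs_calibration: bias = %+.3f ms (from %d training minutes)>\n",
              x$bias_ms, x$n_pairs))
  invisible(x)
}

#' Apply the learned bias to minute estimates
#'
#' Adds `bias_ms` to every non-missing estimate. A `calibrated` attribute
#' guards against double application.
#'
#' @param estimates Numeric minute estimates (ms).
#' @param model An `mqrs_calibration`.
#' @return Calibrated estimates with attribute `calibrated = TRUE`.
#' @export
apply_calibration <- function(estimates, model) {
  stopifnot(inherits(model, "mqrs_calibration"))
  if (isTRUE(attr(estimates, "calibrated")))
    stop("estimates are already calibrated")
  out <- estimates + model$bias_ms
  attr(out, "calibrated") <- TRUE
  out
}

#' Agreement metrics between predicted and reference minute durations
#'
#' Computes, over paired non-missing minutes: the Pearson correlation
#' coefficient (CR, `NA` when the reference has zero variance), the mean
#' error (ME) and its sample standard deviation (STD, `n - 1`
#' denominator), the mean absolute error (MAE), the root mean square
#' error (RMSE), and Bland-Altman limits of agreement
#' (`ME +/- 1.96 * STD`). Errors are `pred - ref` in ms.
#'
#' @param pred Predicted minute durations (ms).
#' @param ref Reference minute durations (ms), same length.
#' @return An object of class `mqrs_metrics`.
#' @export
evaluate_estimates <- function(pred, ref) {
  if (length(pred) != length(ref)) stop("'pred' and 'ref' must be aligned")
  ok <- is.finite(pred) & is.finite(ref)
  if (sum(ok) < 2L) stop("need at least 2 paired non-missing minutes")
  p <- as.numeric(pred[ok]); r <- ref[ok]
  e <- p - r
  me <- mean(e)
  std <- stats::sd(e)
  cr <- if (stats::var(r) > 0 && stats::var(p) > 0) stats::cor(p, r) else NA_real_
  structure(list(cr = cr, me = me, std = std,
                 mae = mean(abs(e)), rmse = sqrt(mean(e^2)),
                 ba_limits = c(lower = me - 1.96 * std, upper = me + 1.96 * std),
                 n = sum(ok), pred = p, ref = r),
            class = "mqrs_metrics")
}

#' @export
print.mqrs_metrics <- function(x, ...) {
  cat(sprintf(
    "QRS duration agreement over %d minutes:\n  CR   %s\n  ME   %+.2f ms (SD %.2f)\n  MAE  %.2f ms\n  RMSE %.2f ms\n  BA limits [%.2f, %.2f] ms\n",
    x$n, if (is.na(x$cr)) "NA" else sprintf("%.1f%%", 100 * x$cr),
    x$me, x$std, x$mae, x$rmse, x$ba_limits[1], x$ba_limits[2]))
  invisible(x)
}

#' Scatter and Bland-Altman plots for an agreement report
#'
#' @param x An `mqrs_metrics` object.
#' @param ... Ignored.
#' @export
plot.mqrs_metrics <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$ref, x$pred, xlab = "Chest QRS duration (ms)",
                 ylab = "Predicted QRS duration (ms)",
                 main = sprintf("CR = %s",
                                if (is.na(x$cr)) "NA" else sprintf("%.1f%%", 100 * x$cr)))
  graphics::abline(0, 1, lty = 2)
  means <- (x$pred + x$ref) / 2
  diffs <- x$pred - x$ref
  graphics::plot(means, diffs, xlab = "Mean of methods (ms)",
                 ylab = "Difference (ms)", main = "Bland-Altman")
  graphics::abline(h = x$me, lty = 1)
  graphics::abline(h = x$ba_limits, lty = 2)
  invisible(x)
}
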