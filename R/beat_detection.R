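#' Detect spike candidates with an adaptive amplitude threshold
#'
#' Heartbeat candidates are local maxima of the absolute filtered signal
#' that exceed a fraction of a moving upper envelope — the 95th percentile
#' of `|x|` over a sliding window (evaluated on a quarter-window hop grid
#' and linearly interpolated to every sample). Candidates closer together
#' than the refractory period are resolved in favour of the larger peak,
#' matching the physiological lower bound on RR intervals.
#'
#' @param rec A bandpass-filtered [ecg_record()].
#' @param refractory_ms Minimum separation between retained candidates (ms).
#' @param window_s Envelope window length in seconds.
#' @param frac Threshold as a fraction of the moving envelope.
#' @return Integer vector of candidate apex sample indices, sorted.
#' @export
detect_spike_candidates <- function(rec, refractory_ms = 250, window_s = 2,
                                    frac = 0.5) {
  stopifnot(inherits(rec, "ecg_record"))
  x <- rec$samples
  n <- length(x)
  win <- round(window_s * rec$fs)
  if (n < win) stop("record shorter than one envelope window")
  ax <- abs(x)

  hop <- max(1L, win %/% 4L)
  centers <- seq(1L, n, by = hop)
  env_pts <- vapply(centers, function(cc) {
    lo <- max(1L, cc - win %/% 2L)
    hi <- min(n, cc + win %/% 2L)
    stats::quantile(ax[lo:hi], 0.95, names = FALSE)
  }, numeric(1))
  env <- stats::approx(centers, env_pts, xout = seq_len(n), rule = 2)$y

  core <- 2:(n - 1L)
  is_max <- ax[core] > ax[core - 1L] & ax[core] >= ax[core + 1L]
  cand <- core[is_max & ax[core] > frac * env[core] & ax[core] > 0]
  if (length(cand) == 0L) return(integer(0))

  # refractory suppression: keep larger peaks first
  refr <- round(refractory_ms / 1000 * rec$fs)
  ord <- cand[order(ax[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (p in ord) {
    if (length(kept) == 0L || all(abs(kept - p) >= refr)) kept <- c(kept, p)
  }
  sort(kept)
}

#' Extract the ten-feature representation of heartbeat candidates
#'
#' Each candidate spike is described by ten features that mix amplitude,
#' morphology, timing and local-SNR information, chosen to stay informative
#' under motion artifacts. In order:
#'
#' 1. apex absolute amplitude;
#' 2. peak-to-peak amplitude in a +/-60 ms window;
#' 3. apex amplitude over the median absolute signal in +/-1 s (local SNR
#'    proxy, capped at 1e4 for a near-zero background);
#' 4. width at half the apex amplitude (ms);
#' 5. maximum absolute slope in +/-60 ms (per sample);
#' 6. signal energy in +/-60 ms over energy in +/-500 ms;
#' 7. interval to the previous candidate (ms; 0 for the first);
#' 8. ratio of that interval to the running median of previous intervals
#'    (1 while undefined);
#' 9. normalized correlation of the +/-60 ms window with the running mean
#'    of the preceding candidates' windows (0 for the first);
#' 10. excess kurtosis of the +/-60 ms window.
#'
#' Candidates whose window is truncated by a record edge are computed on
#' the edge-padded window and flagged in the `truncated` attribute.
#'
#' @param rec A bandpass-filtered [ecg_record()].
#' @param peaks Integer vector of candidate apex indices (sorted).
#' @return Numeric matrix, one row per candidate, columns `f01`..`f10`,
#'   with a logical `truncated` attribute.
#' @export
extract_features <- function(rec, peaks) {
  stopifnot(inherits(rec, "ecg_record"))
  x <- rec$samples
  n <- length(x)
  fs <- rec$fs
  w60 <- max(1L, round(0.060 * fs))
  w500 <- max(w60, round(0.500 * fs))
  w1s <- max(w500, round(1.0 * fs))
  wlen <- 2L * w60 + 1L

  m <- length(peaks)
  out <- matrix(NA_real_, m, 10L,
                dimnames = list(NULL, sprintf("f%02d", 1:10)))
  truncated <- logical(m)
  run_mean <- NULL
  n_seen <- 0L
  intervals <- numeric(0)

  padded_window <- function(p, half) {
    idx <- (p - half):(p + half)
    truncated_here <- idx[1] < 1L || idx[length(idx)] > n
    idx <- pmin(pmax(idx, 1L), n) # edge padding by repetition
    list(vals = x[idx], truncated = truncated_here)
  }

  for (i in seq_len(m)) {
    p <- peaks[i]
    if (p < 1L || p > n) stop("candidate apex outside the record")
    pw <- padded_window(p, w60)
    w <- pw$vals
    truncated[i] <- pw$truncated
    apex <- abs(x[p])

    f1 <- apex
    f2 <- diff(range(w))
    bg <- stats::median(abs(padded_window(p, w1s)$vals))
    f3 <- if (apex == 0) 0 else apex / max(bg, 1e-4 * apex)
    # half-max width by crossing scan on |x|
    half <- apex / 2
    l <- p
    while (l > 1L && abs(x[l - 1L]) >= half) l <- l - 1L
    r <- p
    while (r < n && abs(x[r + 1L]) >= half) r <- r + 1L
    f4 <- (r - l + 1L) / fs * 1000
    f5 <- max(abs(diff(w)))
    e_near <- sum(w^2)
    e_far <- sum(padded_window(p, w500)$vals^2)
    f6 <- e_near / max(e_far, .Machine$double.xmin)
    f7 <- if (i == 1L) 0 else (p - peaks[i - 1L]) / fs * 1000
    f8 <- if (length(intervals) == 0L || f7 == 0) 1 else {
      md <- stats::median(intervals)
      if (md > 0) f7 / md else 1
    }
    f9 <- if (is.null(run_mean)) 0 else {
      if (stats::sd(w) > 0 && stats::sd(run_mean) > 0)
        stats::cor(w, run_mean) else 0
    }
    mu <- mean(w)
    v <- mean((w - mu)^2)
    f10 <- if (v > 0) mean((w - mu)^4) / v^2 - 3 else 0

    out[i, ] <- c(f1, f2, f3, f4, f5, f6, f7, f8, f9, f10)
    if (i > 1L) intervals <- c(intervals, f7)
    run_mean <- if (is.null(run_mean)) w else (run_mean * n_seen + w) / (n_seen + 1L)
    n_seen <- n_seen + 1L
  }
  stopifnot(all(is.finite(out)))
  attr(out, "truncated") <- truncated
  out
}

#' Label candidates against reference R peaks
#'
#' Greedy one-to-one matching: candidate/reference pairs are considered in
#' order of increasing time offset; a candidate is labelled `+1` iff it
#' claims an as-yet-unclaimed reference R peak within `tol_ms`, else `-1`.
#'
#' @param peaks Candidate apex indices (samples).
#' @param reference An [ecg_annotations()] with reference R peaks,
#'   time-aligned with the candidate record.
#' @param fs Sampling rate in Hz.
#' @param tol_ms Matching tolerance in ms.
#' @return Integer vector of labels in `{-1, +1}`, one per candidate.
#' @export
label_candidates <- function(peaks, reference, fs, tol_ms = 75) {
  stopifnot(inherits(reference, "ecg_annotations"))
  refs <- reference$r_peaks
  if (length(refs) == 0L) stop("empty reference annotation")
  tol <- tol_ms / 1000 * fs
  labels <- rep(-1L, length(peaks))
  if (length(peaks) == 0L) return(labels)
  dt <- abs(outer(peaks, refs, "-"))
  pairs <- which(dt <= tol, arr.ind = TRUE)
  if (nrow(pairs) > 0L) {
    pairs <- pairs[order(dt[pairs]), , drop = FALSE]
    cand_used <- logical(length(peaks))
    ref_used <- logical(length(refs))
    for (k in seq_len(nrow(pairs))) {
      ci <- pairs[k, 1L]; ri <- pairs[k, 2L]
      if (!cand_used[ci] && !ref_used[ri]) {
        labels[ci] <- 1L
        cand_used[ci] <- TRUE
        ref_used[ri] <- TRUE
      }
    }
  }
  labels
}

#' Train the linear heartbeat-identification SVM
#'
#' Fits a soft-margin linear support vector machine on standardized
#' features (per-feature center/scale learned here and stored with the
#' model). The returned model holds the support vectors, their labels and
#' nonnegative weights, and the bias, so the decision function
#' `sign(sum_i alpha_i y_i <x, x_i> + b)` can be evaluated explicitly by
#' [svm_predict()].
#'
#' @param X Feature matrix (rows = candidates, 10 columns).
#' @param y Labels in `{-1, +1}`, both classes present.
#' @param C Soft-margin cost.
#' @return An object of class `mqrs_svm`.
#' @export
train_svm <- function(X, y, C = 1.0) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (nrow(X) != length(y) || nrow(X) < 2L)
    stop("need matching X rows and y labels, at least 2")
  if (length(unique(y)) < 2L) stop("both classes must be present to train the SVM")
  center <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scl, "/")
  fit <- e1071::svm(x = Xs, y = factor(y, levels = c(-1L, 1L)),
                    kernel = "linear", cost = C, scale = FALSE)
  alpha_y <- as.numeric(fit$coefs)      # alpha_i * y_i, orientation per libsvm
  b <- -fit$rho
  model <- structure(
    list(support_vectors = unname(as.matrix(fit$SV)), alpha_y = alpha_y,
         bias = b, center = unname(center), scale = unname(scl), C = C),
    class = "mqrs_svm"
  )
  # orient the decision function so positive means class +1
  pred_e1071 <- as.integer(as.character(predict(fit, Xs)))
  agree <- mean(svm_predict(model, X) == pred_e1071)
  if (agree < 0.5) {
    model$alpha_y <- -model$alpha_y
    model$bias <- -model$bias
  }
  model
}

#' @export
print.mqrs_svm <- function(x, ...) {
  cat(sprintf("<mqrs_svm: linear SVM, %d support vectors, %d features, C = %g>\n",
              nrow(x$support_vectors), ncol(x$support_vectors), x$C))
  invisible(x)
}

#' Evaluate the SVM decision function
#'
#' Computes `sum_i alpha_i y_i <x, x_i> + b` on standardized features; see
#' [svm_predict()] for the classification rule.
#'
#' @param model An `mqrs_svm`.
#' @param X Feature matrix or single feature vector.
#' @return Numeric decision values.
#' @export
svm_decision <- function(model, X) {
  stopifnot(inherits(model, "mqrs_svm"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  X <- as.matrix(X)
  if (ncol(X) != ncol(model$support_vectors))
    stop("feature dimension does not match the trained model")
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  as.numeric(Xs %*% t(model$support_vectors) %*% model$alpha_y + model$bias)
}

#' Classify heartbeat candidates with the trained SVM
#'
#' Returns the sign of the decision function, with `sign(0)` defined as
#' `+1` (a candidate exactly on the boundary is kept as a heartbeat).
#'
#' @inheritParams svm_decision
#' @return Integer labels in `{-1, +1}`.
#' @export
svm_predict <- function(model, X) {
  d <- svm_decision(model, X)
  ifelse(d >= 0, 1L, -1L)
}

#' Segment R-to-R heartbeats
#'
#' Beat segments run from one accepted R peak to the next (half-open
#' ranges), so each segment contains the second half of one heartbeat and
#' the first half of the following one; `n` peaks yield `n - 1` segments.
#' The R peak is used as the segment boundary because it is the most
#' distinguishable landmark in a weak mobile ECG.
#'
#' @param rec An [ecg_record()].
#' @param peaks Sorted accepted R-peak sample indices (>= 2).
#' @return A data.frame with columns `start`, `end` (half-open, samples)
#'   and `length`.
#' @export
segment_heartbeats <- function(rec, peaks) {
  stopifnot(inherits(rec, "ecg_record"))
  peaks <- as.integer(peaks)
  if (length(peaks) < 2L) stop("need at least 2 accepted R peaks to segment")
  if (any(diff(peaks) <= 0L)) stop("'peaks' must be strictly increasing")
  if (peaks[1] < 1L || peaks[length(peaks)] > length(rec$samples))
    stop("'peaks' outside the record")
  n <- length(peaks)
  data.frame(start = peaks[-n], end = peaks[-1],
             length = diff(peaks))
}
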