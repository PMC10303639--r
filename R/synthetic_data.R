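#' Configuration for the synthetic paired-ECG generator
#'
#' Defines the study conditions emulated by [generate_session()]: paired
#' chest/mobile recordings laid out as `n_trials` trials of
#' `trial_minutes` minutes, a mobile lead at 2--5% of the chest
#' amplitude, baseline wander plus broadband noise, a 20-second motion
#' artifact burst in the evaluation minute of every trial, occasional
#' false spikes, and a fixed mobile-vs-chest QRS-duration offset.
#'
#' @param fs Sampling rate (Hz).
#' @param n_trials Trials per session.
#' @param trial_minutes Minutes per trial.
#' @param hr_base Baseline heart rate (bpm).
#' @param hr_drift_bpm Amplitude of the slow sinusoidal heart-rate drift.
#' @param hr_drift_period_s Period of the drift (s).
#' @param rr_jitter_ms SD of beat-to-beat RR jitter (ms).
#' @param qrs_mean_ms,qrs_sd_ms Mean and beat-to-beat SD of the true
#'   chest QRS duration (ms).
#' @param qrs_drift_ms,qrs_drift_period_s Amplitude and period of a slow
#'   sinusoidal modulation of the mean QRS duration across the session
#'   (random phase per session), emulating the gradual duration changes
#'   seen under an exercise protocol; this is what gives evaluation
#'   minutes genuinely different true durations.
#' @param mobile_scale Mobile amplitude relative to chest (in (0, 1);
#'   physiologic range roughly 0.02--0.05).
#' @param lead_bias_ms Mobile-minus-chest QRS-duration offset (ms).
#' @param noise_sd Broadband noise SD on the mobile lead (chest-mV units;
#'   compare with the mobile R amplitude `mobile_scale`).
#' @param wander_amp,wander_freq Baseline-wander amplitude and frequency.
#' @param chest_noise_sd Broadband noise SD on the chest lead.
#' @param artifact_start_s Burst onset within each trial (s).
#' @param artifact_len_s Burst length (s).
#' @param artifact_gain Noise multiplier inside bursts.
#' @param false_spike_rate Expected false spikes per minute.
#' @param eval_minute Which minute of each trial is the evaluation minute.
#' @param subject_id Subject label.
#' @param seed RNG seed used by [generate_session()].
#' @return An object of class `mqrs_synth_config`.
#' @export
synth_config <- function(fs = 500, n_trials = 15, trial_minutes = 2,
                         hr_base = 70, hr_drift_bpm = 4,
                         hr_drift_period_s = 60, rr_jitter_ms = 15,
                         qrs_mean_ms = 95, qrs_sd_ms = 5,
                         qrs_drift_ms = 6, qrs_drift_period_s = 420,
                         mobile_scale = 0.03, lead_bias_ms = 8,
                         noise_sd = 0.003, wander_amp = 0.01,
                         wander_freq = 0.33, chest_noise_sd = 0.005,
                         artifact_start_s = 60, artifact_len_s = 20,
                         artifact_gain = 8, false_spike_rate = 2,
                         eval_minute = 2, subject_id = "synth01",
                         seed = 1L) {
  cfg <- list(fs = fs, n_trials = n_trials, trial_minutes = trial_minutes,
              hr_base = hr_base, hr_drift_bpm = hr_drift_bpm,
              hr_drift_period_s = hr_drift_period_s,
              rr_jitter_ms = rr_jitter_ms, qrs_mean_ms = qrs_mean_ms,
              qrs_sd_ms = qrs_sd_ms, qrs_drift_ms = qrs_drift_ms,
              qrs_drift_period_s = qrs_drift_period_s,
              mobile_scale = mobile_scale,
              lead_bias_ms = lead_bias_ms, noise_sd = noise_sd,
              wander_amp = wander_amp, wander_freq = wander_freq,
              chest_noise_sd = chest_noise_sd,
              artifact_start_s = artifact_start_s,
              artifact_len_s = artifact_len_s,
              artifact_gain = artifact_gain,
              false_spike_rate = false_spike_rate,
              eval_minute = eval_minute, subject_id = subject_id,
              seed = seed)
  with(cfg, {
    stopifnot(fs > 0, n_trials >= 1, trial_minutes >= 1, hr_base > 0,
              qrs_mean_ms > 0, qrs_sd_ms >= 0,
              mobile_scale > 0, mobile_scale < 1,
              noise_sd >= 0, artifact_len_s >= 0, artifact_gain >= 1,
              false_spike_rate >= 0,
              eval_minute >= 1, eval_minute <= trial_minutes,
              artifact_start_s + artifact_len_s <= trial_minutes * 60)
    max_qrs_s <- (qrs_mean_ms + qrs_drift_ms + 4 * qrs_sd_ms +
                    abs(lead_bias_ms)) / 1000
    if (max_qrs_s >= 60 / (hr_base + hr_drift_bpm))
      stop("QRS duration incompatible with the RR interval")
  })
  structure(cfg, class = "mqrs_synth_config")
}

#' @export
print.mqrs_synth_config <- function(x, ...) {
  cat(sprintf(
    "<mqrs_synth_config: %d x %d min @ %g Hz, HR %g bpm, QRS %g+/-%g ms, mobile scale %.3g, lead bias %g ms>\n",
    x$n_trials, x$trial_minutes, x$fs, x$hr_base, x$qrs_mean_ms,
    x$qrs_sd_ms, x$mobile_scale, x$lead_bias_ms))
  invisible(x)
}

# Gaussian-wavelet beat synthesizer. schedule: data.frame with t_r (s) and
# qrs duration d_s (s) per beat. Returns the signal vector.
.synth_wave <- function(n, fs, schedule, amp_scale = 1) {
  sig <- numeric(n)
  add_gauss <- function(tc, sigma, amp) {
    lo <- max(1L, floor((tc - 4 * sigma) * fs) + 1L)
    hi <- min(n, ceiling((tc + 4 * sigma) * fs) + 1L)
    if (lo > hi) return(invisible())
    tt <- (lo:hi - 1) / fs
    sig[lo:hi] <<- sig[lo:hi] + amp * exp(-(tt - tc)^2 / (2 * sigma^2))
    invisible()
  }
  for (i in seq_len(nrow(schedule))) {
    tr <- schedule$t_r[i]
    d <- schedule$d_s[i]
    sq <- 0.09 * d
    add_gauss(tr - 0.18, 0.025, 0.12 * amp_scale)            # P
    add_gauss(tr - 0.45 * d + 2 * sq, sq, -0.12 * amp_scale) # Q
    add_gauss(tr, 0.010, 1.00 * amp_scale)                   # R
    add_gauss(tr + 0.55 * d - 2 * sq, sq, -0.22 * amp_scale) # S
    add_gauss(tr + 0.30, 0.060, 0.30 * amp_scale)            # T
  }
  sig
}

#' Generate a chest-lead ECG with exact per-beat ground truth
#'
#' Each heartbeat is a sum of five Gaussian wavelets at the P/Q/R/S/T
#' characteristic points; the true QRS duration of each beat is drawn
#' from the configured distribution and realized analytically: the QRS
#' onset is the Q-wave centre minus two Q sigmas and the offset the
#' S-wave centre plus two S sigmas, so the ground-truth boundaries are
#' exact by construction (`qrs_on < r_peak < qrs_off` always). RR
#' intervals follow the drifting heart rate plus beat-to-beat jitter.
#' Uses R's RNG; seed beforehand (or use [generate_session()]).
#'
#' @param config An [synth_config()].
#' @param session `"training"` or `"testing"` (label only).
#' @param duration_s Optional recording length override (s); defaults to
#'   the configured trial layout.
#' @return List with `record` (an [ecg_record()]) and `truth` (an
#'   `mqrs_truth`: per-beat table, artifact intervals, false-spike
#'   registry — empty for the chest lead).
#' @export
generate_chest_ecg <- function(config, session = "training",
                               duration_s = NULL) {
  stopifnot(inherits(config, "mqrs_synth_config"))
  dur <- if (is.null(duration_s)) config$n_trials * config$trial_minutes * 60
         else duration_s
  n <- round(dur * config$fs)

  t_r <- numeric(0)
  t <- 0.5
  while (t <= dur - 0.5) {
    t_r <- c(t_r, t)
    hr <- config$hr_base +
      config$hr_drift_bpm * sin(2 * pi * t / config$hr_drift_period_s)
    rr <- 60 / hr + stats::rnorm(1, 0, config$rr_jitter_ms / 1000)
    t <- t + max(rr, 0.35)
  }
  nb <- length(t_r)
  drift_phase <- stats::runif(1, 0, 2 * pi)
  d_mean <- config$qrs_mean_ms + config$qrs_drift_ms *
    sin(2 * pi * t_r / config$qrs_drift_period_s + drift_phase)
  d_ms <- stats::rnorm(nb, d_mean, config$qrs_sd_ms)
  d_ms <- pmin(pmax(d_ms, 40), 180)
  sched <- data.frame(t_r = t_r, d_s = d_ms / 1000)

  sig <- .synth_wave(n, config$fs, sched) +
    stats::rnorm(n, 0, config$chest_noise_sd)
  rec <- ecg_record(sig, fs = config$fs, role = "chest",
                    subject_id = config$subject_id, session = session)

  beats <- data.frame(
    t_r = t_r,
    r_peak = round(t_r * config$fs) + 1L,
    qrs_on_s = t_r - 0.45 * sched$d_s,
    qrs_off_s = t_r + 0.55 * sched$d_s,
    duration_ms = d_ms
  )
  beats$qrs_on <- round(beats$qrs_on_s * config$fs) + 1L
  beats$qrs_off <- round(beats$qrs_off_s * config$fs) + 1L
  beats$is_clean <- TRUE
  truth <- structure(
    list(beats = beats, artifact_intervals = NULL,
         false_spike_indices = integer(0), fs = config$fs,
         duration_s = dur, lead_bias_ms = 0),
    class = "mqrs_truth")
  list(record = rec, truth = truth)
}

#' Derive the paired mobile-lead ECG
#'
#' Re-synthesizes the same beat train at `mobile_scale` of the chest
#' amplitude with every QRS duration widened by `lead_bias_ms` (Q/S
#' wavelet widths re-derived, so the mobile ground-truth boundaries stay
#' exact), then degrades it: baseline wander, broadband noise (multiplied
#' by `artifact_gain` inside the per-trial motion-artifact burst, plus a
#' motion sway component), and false spikes at `false_spike_rate` per
#' minute placed away from true R peaks. Uses R's RNG.
#'
#' @param chest_truth The `truth` component returned by
#'   [generate_chest_ecg()].
#' @param config The same [synth_config()].
#' @param session Session label.
#' @return List with `record` (mobile [ecg_record()]) and `truth` (an
#'   `mqrs_truth` with mobile-channel boundaries, artifact intervals,
#'   false-spike registry and per-beat cleanliness flags).
#' @export
derive_mobile_ecg <- function(chest_truth, config, session = "training") {
  stopifnot(inherits(chest_truth, "mqrs_truth"),
            inherits(config, "mqrs_synth_config"))
  fs <- config$fs
  dur <- chest_truth$duration_s
  n <- round(dur * fs)
  cb <- chest_truth$beats

  d_m_ms <- cb$duration_ms + config$lead_bias_ms
  sched <- data.frame(t_r = cb$t_r, d_s = d_m_ms / 1000)
  sig <- .synth_wave(n, fs, sched, amp_scale = config$mobile_scale)

  tt <- (seq_len(n) - 1) / fs
  sig <- sig + config$wander_amp *
    sin(2 * pi * config$wander_freq * tt + stats::runif(1, 0, 2 * pi))

  trial_len <- config$trial_minutes * 60
  art <- data.frame(
    start_s = (seq_len(config$n_trials) - 1) * trial_len + config$artifact_start_s,
    end_s = (seq_len(config$n_trials) - 1) * trial_len + config$artifact_start_s +
      config$artifact_len_s)
  noise <- stats::rnorm(n, 0, config$noise_sd)
  in_burst <- rep(FALSE, n)
  for (b in seq_len(nrow(art))) {
    lo <- floor(art$start_s[b] * fs) + 1L
    hi <- min(n, ceiling(art$end_s[b] * fs))
    if (config$artifact_len_s > 0 && lo <= hi) in_burst[lo:hi] <- TRUE
  }
  noise[in_burst] <- noise[in_burst] * config$artifact_gain
  sway <- config$wander_amp * config$artifact_gain *
    sin(2 * pi * 1.1 * tt + stats::runif(1, 0, 2 * pi))
  sig <- sig + noise + ifelse(in_burst, sway, 0)

  total_min <- dur / 60
  n_fs <- stats::rpois(1, config$false_spike_rate * total_min)
  fs_idx <- integer(0)
  if (n_fs > 0) {
    cand_t <- stats::runif(n_fs, 0.5, dur - 0.5)
    # keep spikes away from true R peaks so they are unambiguous negatives
    keep <- vapply(cand_t, function(x) min(abs(x - cb$t_r)) > 0.2, logical(1))
    cand_t <- cand_t[keep]
    for (tc in cand_t) {
      amp <- config$mobile_scale * stats::runif(1, 0.9, 1.6) *
        sample(c(-1, 1), 1)
      lo <- max(1L, floor((tc - 0.05) * fs) + 1L)
      hi <- min(n, ceiling((tc + 0.05) * fs) + 1L)
      ts <- (lo:hi - 1) / fs
      sig[lo:hi] <- sig[lo:hi] + amp * exp(-(ts - tc)^2 / (2 * 0.012^2))
    }
    fs_idx <- round(cand_t * fs) + 1L
  }

  rec <- ecg_record(sig, fs = fs, role = "mobile",
                    subject_id = config$subject_id, session = session)
  beats <- cb
  beats$duration_ms <- d_m_ms
  beats$qrs_on_s <- cb$t_r - 0.45 * sched$d_s
  beats$qrs_off_s <- cb$t_r + 0.55 * sched$d_s
  beats$qrs_on <- round(beats$qrs_on_s * fs) + 1L
  beats$qrs_off <- round(beats$qrs_off_s * fs) + 1L
  beats$duration_chest_ms <- cb$duration_ms
  beats$is_clean <- !vapply(cb$t_r, function(x)
    any(x >= art$start_s & x < art$end_s), logical(1))
  truth <- structure(
    list(beats = beats, artifact_intervals = art,
         false_spike_indices = sort(fs_idx), fs = fs, duration_s = dur,
         lead_bias_ms = config$lead_bias_ms),
    class = "mqrs_truth")
  list(record = rec, truth = truth)
}

#' @export
print.mqrs_truth <- function(x, ...) {
  cat(sprintf("<mqrs_truth: %d beats over %.0f s, %d false spikes, lead bias %g ms>\n",
              nrow(x$beats), x$duration_s, length(x$false_spike_indices),
              x$lead_bias_ms))
  invisible(x)
}

#' Generate a paired training + testing synthetic session
#'
#' Two independent paired chest/mobile recordings sharing all
#' subject-level parameters (heart rate, lead bias, mobile scale) with
#' fresh noise realizations, fully reproducible from `config$seed`.
#'
#' @param config An [synth_config()].
#' @return An object of class `mqrs_session`: list with `training` and
#'   `testing` (each `list(chest, mobile, truth)` where `truth` is the
#'   mobile-channel ground truth and `chest$truth` the chest one), and
#'   the `config`.
#' @export
generate_session <- function(config = synth_config()) {
  stopifnot(inherits(config, "mqrs_synth_config"))
  set.seed(config$seed)
  make <- function(session) {
    ch <- generate_chest_ecg(config, session = session)
    mo <- derive_mobile_ecg(ch$truth, config, session = session)
    list(chest = ch$record, chest_truth = ch$truth,
         mobile = mo$record, truth = mo$truth)
  }
  structure(list(training = make("training"), testing = make("testing"),
                 config = config),
            class = "mqrs_session")
}

#' @export
print.mqrs_session <- function(x, ...) {
  cat("<mqrs_session>\n  config: ")
  print(x$config)
  cat(sprintf("  training: %d beats; testing: %d beats\n",
              nrow(x$training$truth$beats), nrow(x$testing$truth$beats)))
  invisible(x)
}

#' Evaluation-minute windows of a session layout
#'
#' One window per trial: the configured evaluation minute (by default the
#' second minute, which also contains the artifact burst).
#'
#' @param config An [synth_config()].
#' @return Data.frame with `start_s`, `end_s` per trial.
#' @export
eval_minute_spans <- function(config) {
  stopifnot(inherits(config, "mqrs_synth_config"))
  trial_len <- config$trial_minutes * 60
  start <- (seq_len(config$n_trials) - 1) * trial_len +
    (config$eval_minute - 1) * 60
  data.frame(start_s = start, end_s = start + 60)
}

#' Ground truth as an annotation track
#'
#' @param truth An `mqrs_truth`.
#' @return An [ecg_annotations()] with R peaks and QRS boundaries.
#' @export
truth_annotations <- function(truth) {
  stopifnot(inherits(truth, "mqrs_truth"))
  ecg_annotations(r_peaks = truth$beats$r_peak,
                  qrs_on = truth$beats$qrs_on,
                  qrs_off = truth$beats$qrs_off)
}

#' True per-window mean QRS durations
#'
#' @param truth An `mqrs_truth`.
#' @param spans Windows (`start_s`/`end_s`), e.g. [eval_minute_spans()].
#' @param channel Use the truth's own durations (`"own"`) or, for a
#'   mobile truth, the paired chest durations (`"chest"`).
#' @return Numeric vector of per-window means (ms), `NA` where empty.
#' @export
truth_minute_durations <- function(truth, spans, channel = c("own", "chest")) {
  stopifnot(inherits(truth, "mqrs_truth"))
  channel <- match.arg(channel)
  dd <- if (channel == "chest") {
    if (is.null(truth$beats$duration_chest_ms))
      stop("this truth has no paired chest durations")
    truth$beats$duration_chest_ms
  } else truth$beats$duration_ms
  vapply(seq_len(nrow(spans)), function(w) {
    sel <- truth$beats$t_r >= spans$start_s[w] & truth$beats$t_r < spans$end_s[w]
    if (any(sel)) mean(dd[sel]) else NA_real_
  }, numeric(1))
}
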