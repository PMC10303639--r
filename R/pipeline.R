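#' Pipeline configuration
#'
#' Tunable parameters of the estimation pipeline, with the defaults used
#' throughout: 2--30 Hz order-6 zero-phase bandpass; adaptive-threshold
#' spike detection (2 s envelope window, half-envelope threshold, 250 ms
#' refractory); 75 ms truth-matching tolerance and unit SVM cost; beats
#' resampled to a common 512-sample grid (finer than the native sampling
#' at resting heart rates, so boundary transfer is never quantization-
#' limited) with a 10-sample angle gap; K = 3 medoid clusters; 50
#' histogram bins and order-10 distortion smoothing; 300 ms sanity bound
#' on per-beat durations.
#'
#' @param resampled_len Common resampled beat length (samples).
#' @param K Number of K-medoid clusters.
#' @param angle_gap Angle-view neighbour distance (samples).
#' @param svm_C SVM soft-margin cost.
#' @param tol_ms Candidate-to-reference matching tolerance (ms).
#' @param refractory_ms,window_s,frac Spike-detection parameters, see
#'   [detect_spike_candidates()].
#' @param low,high,filter_order Bandpass parameters, see
#'   [bandpass_filter()].
#' @param nbins Histogram bins for [triangle_threshold()].
#' @param smooth_order Moving-average order for [smooth_distortions()].
#' @param sanity_ms Upper sanity bound on per-beat QRS durations (ms).
#' @param verbose Emit per-stage beat counts as messages.
#' @return An object of class `mqrs_config`.
#' @export
mqrs_config <- function(resampled_len = 512, K = 3, angle_gap = 10,
                        svm_C = 1.0, tol_ms = 75, refractory_ms = 250,
                        window_s = 2, frac = 0.5, low = 2, high = 30,
                        filter_order = 6, nbins = 50, smooth_order = 10,
                        sanity_ms = 300, verbose = FALSE) {
  structure(list(resampled_len = resampled_len, K = K,
                 angle_gap = angle_gap, svm_C = svm_C, tol_ms = tol_ms,
                 refractory_ms = refractory_ms, window_s = window_s,
                 frac = frac, low = low, high = high,
                 filter_order = filter_order, nbins = nbins,
                 smooth_order = smooth_order, sanity_ms = sanity_ms,
                 verbose = verbose),
            class = "mqrs_config")
}

.say <- function(config, fmt, ...) {
  if (isTRUE(config$verbose)) message(sprintf(fmt, ...))
}

#' Per-beat reference durations averaged over windows
#'
#' Computes per-beat QRS durations from an annotation track with QRS
#' boundaries and averages them over the given windows — the chest-lead
#' reference minute durations used for calibration and evaluation.
#'
#' @param ann An [ecg_annotations()] with `qrs_on`/`qrs_off`.
#' @param fs Sampling rate (Hz).
#' @param spans Windows (`start_s`/`end_s`).
#' @return Numeric vector of per-window mean durations (ms), `NA` where
#'   empty.
#' @export
annotation_minute_durations <- function(ann, fs, spans) {
  stopifnot(inherits(ann, "ecg_annotations"))
  if (is.null(ann$qrs_on)) stop("annotations carry no QRS boundaries")
  dur <- (ann$qrs_off - ann$qrs_on) / fs * 1000
  tt <- (ann$r_peaks - 1) / fs
  vapply(seq_len(nrow(spans)), function(w) {
    sel <- tt >= spans$start_s[w] & tt < spans$end_s[w]
    if (any(sel)) mean(dur[sel]) else NA_real_
  }, numeric(1))
}

# Stage I on a filtered record: detect candidates and keep SVM-accepted ones.
.detect_accept <- function(filt, svm, config) {
  cand <- detect_spike_candidates(filt, refractory_ms = config$refractory_ms,
                                  window_s = config$window_s,
                                  frac = config$frac)
  if (length(cand) < 2L) stop("stage detect_spike_candidates: too few candidates")
  X <- extract_features(filt, cand)
  accepted <- cand[svm_predict(svm, X) == 1L]
  list(candidates = cand, accepted = accepted)
}

# Warp every beat of a beat set against the template.
.warp_all <- function(beats, template, single_view = FALSE) {
  n <- length(beats$views)
  out <- data.frame(qrs_off = rep(NA_integer_, n), qrs_on = NA_integer_,
                    distortion = NA_real_, degenerate = beats$degenerate,
                    collapsed = FALSE)
  for (j in seq_len(n)) {
    if (beats$degenerate[j]) next
    w <- mv_dtw(beats$views[[j]], template, single_view = single_view)
    out$qrs_off[j] <- w$qrs_off
    out$qrs_on[j] <- w$qrs_on
    out$distortion[j] <- w$distortion
    out$collapsed[j] <- w$collapsed
  }
  out
}

# Distortions -> normalized pi, smoothed eta, SQI flags.
.quality <- function(warps, reference_max, tau, config) {
  pi_ <- normalize_distortions(warps$distortion, reference_max)
  eta <- smooth_distortions(pi_, A = config$smooth_order)
  sqi <- compute_sqi(pi_, eta, tau)
  sqi[warps$degenerate | warps$collapsed] <- 0L
  list(pi = pi_, eta = eta, sqi = sqi)
}

# Full training computation; returns all intermediates so that the
# ablation runner can reuse them. template_ann supplies the QRS boundaries
# used to annotate the template (defaults to the chest reference).
.mqrs_train_core <- function(mobile, chest_ann, spans, config,
                             template_ann = NULL) {
  stopifnot(inherits(mobile, "ecg_record"),
            inherits(chest_ann, "ecg_annotations"))
  if (is.null(template_ann)) template_ann <- chest_ann
  if (is.null(chest_ann$qrs_on))
    stop("stage label_candidates: chest reference must carry QRS boundaries")
  fs <- mobile$fs
  filt <- bandpass_filter(mobile, low = config$low, high = config$high,
                          order = config$filter_order)
  cand <- detect_spike_candidates(filt, refractory_ms = config$refractory_ms,
                                  window_s = config$window_s,
                                  frac = config$frac)
  if (length(cand) < 2L) stop("stage detect_spike_candidates: too few candidates")
  X <- extract_features(filt, cand)
  y <- label_candidates(cand, chest_ann, fs = fs, tol_ms = config$tol_ms)
  svm <- train_svm(X, y, C = config$svm_C)
  accepted <- cand[svm_predict(svm, X) == 1L]
  .say(config, "stage I: %d candidates -> %d SVM-accepted heartbeats",
       length(cand), length(accepted))
  if (length(accepted) < config$K + 2L)
    stop("stage train_svm: too few accepted heartbeats")

  segs <- segment_heartbeats(filt, accepted)
  beats <- beat_set(filt, segs, length = config$resampled_len,
                    angle_gap = config$angle_gap)
  template <- learn_template(beats, K = config$K)
  cl <- attr(template, "clustering")
  # annotate the selected medoid; if its segment has no matching reference
  # beat pair, fall back to the remaining medoids by cluster size
  meds <- cl$medoids[order(-vapply(cl$medoids, function(m)
    sum(cl$assignment == m), integer(1)))]
  template_try <- template
  annotated <- NULL
  for (m in unique(c(template$beat_index, meds))) {
    template_try$beat_index <- m
    template_try$views <- beats$views[[m]]
    template_try$segment <- beats$segments[m, , drop = FALSE]
    annotated <- tryCatch(
      annotate_template_boundaries(template_try, reference = template_ann, fs = fs),
      error = function(e) NULL)
    if (!is.null(annotated)) break
  }
  if (is.null(annotated))
    stop("stage annotate_template_boundaries: no medoid matches the reference")
  template <- annotated
  .say(config, "stage II: template beat %d (cluster share %.0f%%), boundaries %d/%d",
       template$beat_index, 100 * template$cluster_share,
       template$qrs_temp_off, template$qrs_temp_on)

  warps <- .warp_all(beats, template)
  reference_max <- max(warps$distortion, na.rm = TRUE)
  pi_ <- normalize_distortions(warps$distortion, reference_max)
  tau <- triangle_threshold(pi_, nbins = config$nbins)$tau
  q <- .quality(warps, reference_max, tau, config)
  .say(config, "stage II: tau = %.3f, %d/%d beats SQI = 1",
       tau, sum(q$sqi), length(q$sqi))

  durations <- beat_qrs_durations(segs, warps, q$sqi, fs,
                                  resampled_len = config$resampled_len,
                                  sanity_ms = config$sanity_ms)
  minutes <- minute_average(durations, spans)
  chest_minutes <- annotation_minute_durations(chest_ann, fs, spans)
  calibration <- fit_bias(minutes$estimate_ms, chest_minutes)
  .say(config, "stage III: bias %+.2f ms from %d minutes",
       calibration$bias_ms, calibration$n_pairs)

  list(filt = filt, candidates = cand, labels = y, svm = svm,
       accepted = accepted, segments = segs, beats = beats,
       template = template, warps = warps, reference_max = reference_max,
       tau = tau, quality = q, durations = durations, minutes = minutes,
       chest_minutes = chest_minutes, calibration = calibration,
       spans = spans, fs = fs, config = config)
}

#' Fit the per-subject QRS estimation model
#'
#' Trains all learned components on one subject's training session: the
#' heartbeat-identification SVM (against the time-aligned chest-lead
#' annotations), the heartbeat template (K-medoid clustering of the
#' SVM-accepted beats, boundaries transferred from the chest
#' annotations), the distortion normalization constant and triangle
#' threshold, and the mobile-to-chest duration bias. The returned model
#' is frozen: [predict.mqrs_fit()] applies it to a testing session
#' without re-learning anything.
#'
#' @param mobile Training-session mobile [ecg_record()] (raw; filtering
#'   is part of the pipeline).
#' @param chest_ann Time-aligned chest-lead [ecg_annotations()] with QRS
#'   boundaries.
#' @param spans Evaluation windows for the training session
#'   (`start_s`/`end_s` data.frame, e.g. [eval_minute_spans()]).
#' @param config An [mqrs_config()].
#' @param template_ann Optional annotation track supplying the QRS
#'   boundaries used to annotate the template beat. Defaults to
#'   `chest_ann`. When per-beat boundaries of the mobile lead itself are
#'   available (e.g. the exact ground truth of a synthetic session), pass
#'   them here: the located durations then measure the mobile lead's own
#'   QRS and the entire lead bias is left to the calibration stage,
#'   instead of being partially absorbed during boundary transfer.
#' @return An object of class `mqrs_fit`.
#' @export
mqrs_fit <- function(mobile, chest_ann, spans, config = mqrs_config(),
                     template_ann = NULL) {
  core <- .mqrs_train_core(mobile, chest_ann, spans, config, template_ann)
  structure(
    list(svm = core$svm, template = core$template,
         reference_max = core$reference_max, tau = core$tau,
         calibration = core$calibration, config = config,
         fs = core$fs, subject_id = mobile$subject_id,
         counts = c(candidates = length(core$candidates),
                    accepted = length(core$accepted),
                    sqi_retained = sum(core$quality$sqi),
                    duration_valid = sum(core$durations$valid)),
         training = list(minutes = core$minutes,
                         chest_minutes = core$chest_minutes,
                         durations = core$durations,
                         pi = core$quality$pi, sqi = core$quality$sqi)),
    class = "mqrs_fit")
}

#' @export
print.mqrs_fit <- function(x, ...) {
  cat(sprintf("Mobile-ECG QRS model for subject %s (fs = %g Hz)\n",
              x$subject_id, x$fs))
  cat(sprintf("  SVM: %d support vectors; template: beat %d (share %.0f%%)\n",
              nrow(x$svm$support_vectors), x$template$beat_index,
              100 * x$template$cluster_share))
  cat(sprintf("  distortion: reference max %.4g, tau = %.3f\n",
              x$reference_max, x$tau))
  cat(sprintf("  calibration bias: %+.2f ms\n", x$calibration$bias_ms))
  cat(sprintf("  training counts: %s\n",
              paste(names(x$counts), x$counts, sep = "=", collapse = ", ")))
  invisible(x)
}

#' @export
summary.mqrs_fit <- function(object, ...) {
  print(object)
  tm <- evaluate_estimates(
    apply_calibration(object$training$minutes$estimate_ms, object$calibration),
    object$training$chest_minutes)
  cat("\nTraining-session agreement (calibrated):\n")
  print(tm)
  invisible(object)
}

#' @export
coef.mqrs_fit <- function(object, ...) {
  c(bias_ms = object$calibration$bias_ms, tau = object$tau,
    reference_max = object$reference_max)
}

#' Plot the learned heartbeat template
#'
#' @param x An `mqrs_fit`.
#' @param ... Ignored.
#' @export
plot.mqrs_fit <- function(x, ...) {
  v <- x$template$views
  op <- graphics::par(mfrow = c(3, 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(op))
  for (l in 1:3) {
    graphics::plot(v[l, ], type = "l", ylab = rownames(v)[l], xlab = "")
    graphics::abline(v = c(x$template$qrs_temp_off, x$template$qrs_temp_on),
                     lty = 2)
  }
  invisible(x)
}

#' Apply a fitted model to a testing session
#'
#' Runs the frozen pipeline on a new mobile recording: filter, detect and
#' SVM-classify spike candidates, segment and warp beats against the
#' stored template, flag beat quality against the stored threshold,
#' assemble durations, average per window, and apply the stored bias.
#' When chest-reference minute durations are supplied, agreement metrics
#' are computed.
#'
#' @param object An `mqrs_fit`.
#' @param mobile Testing-session mobile [ecg_record()].
#' @param spans Evaluation windows for the testing session.
#' @param reference Optional chest-reference minute durations (ms), one
#'   per window.
#' @param calibrate Apply the bias (default `TRUE`).
#' @param ... Ignored.
#' @return An object of class `mqrs_estimate`: per-beat table, per-window
#'   estimates (raw and calibrated), SQI summary, and `metrics` when a
#'   reference was given (`NULL` when every window is missing — metrics
#'   are refused, not fabricated).
#' @export
predict.mqrs_fit <- function(object, mobile, spans, reference = NULL,
                             calibrate = TRUE, ...) {
  stopifnot(inherits(mobile, "ecg_record"))
  config <- object$config
  if (!isTRUE(all.equal(mobile$fs, object$fs)))
    stop("sampling rate of the record does not match the model")
  filt <- bandpass_filter(mobile, low = config$low, high = config$high,
                          order = config$filter_order)
  st1 <- .detect_accept(filt, object$svm, config)
  if (length(st1$accepted) < 3L) stop("too few accepted heartbeats")
  segs <- segment_heartbeats(filt, st1$accepted)
  beats <- beat_set(filt, segs, length = config$resampled_len,
                    angle_gap = config$angle_gap)
  warps <- .warp_all(beats, object$template)
  q <- .quality(warps, object$reference_max, object$tau, config)
  durations <- beat_qrs_durations(segs, warps, q$sqi, object$fs,
                                  resampled_len = config$resampled_len,
                                  sanity_ms = config$sanity_ms)
  minutes <- minute_average(durations, spans)
  est <- minutes$estimate_ms
  if (calibrate) est <- apply_calibration(est, object$calibration)
  minutes$calibrated_ms <- as.numeric(est)
  metrics <- NULL
  if (!is.null(reference)) {
    if (sum(is.finite(est) & is.finite(reference)) < 2L) {
      warning("all evaluation windows missing after purification; metrics not computed")
    } else {
      metrics <- evaluate_estimates(est, reference)
    }
  }
  structure(
    list(beats = durations, minutes = minutes, calibrated = calibrate,
         metrics = metrics, sqi = q$sqi, pi = q$pi, segments = segs,
         counts = c(candidates = length(st1$candidates),
                    accepted = length(st1$accepted),
                    sqi_retained = sum(q$sqi),
                    duration_valid = sum(durations$valid))),
    class = "mqrs_estimate")
}

#' @export
print.mqrs_estimate <- function(x, ...) {
  cat(sprintf("<mqrs_estimate: %d windows (%d with estimates), %scalibrated>\n",
              nrow(x$minutes), sum(is.finite(x$minutes$estimate_ms)),
              if (x$calibrated) "" else "not "))
  cat(sprintf("  counts: %s\n",
              paste(names(x$counts), x$counts, sep = "=", collapse = ", ")))
  if (!is.null(x$metrics)) print(x$metrics)
  invisible(x)
}

#' Table-style ablation over warping views, purification and calibration
#'
#' Evaluates the eight configurations {single-view DTW, multiview DTW} x
#' {with/without SQI purification} x {with/without bias calibration} on
#' the same testing windows. Single-view DTW restricts the warp to the
#' amplitude view; its distortion normalization and threshold are
#' re-learned on the training session under the same restriction. All
#' learning uses the training session only.
#'
#' @param session An `mqrs_session` from [generate_session()], or a list
#'   with the same `training`/`testing` structure.
#' @param config An [mqrs_config()].
#' @param template_source Annotate the template from the mobile lead's
#'   ground-truth boundaries (`"mobile"`, default — the session's exact
#'   truth, so the lead bias is left entirely to calibration) or from
#'   the chest reference (`"chest"`).
#' @return A data.frame with one row per configuration: `approach`,
#'   `cr`, `me`, `std`, `mae`, `rmse` (errors in ms, `cr` a correlation
#'   in [-1, 1]).
#' @export
mqrs_ablation <- function(session, config = mqrs_config(),
                          template_source = c("mobile", "chest")) {
  template_source <- match.arg(template_source)
  spans <- eval_minute_spans(session$config)
  train <- session$training
  test <- session$testing
  chest_ann <- truth_annotations(train$chest_truth)
  template_ann <- if (template_source == "mobile")
    truth_annotations(train$truth) else chest_ann
  core <- .mqrs_train_core(train$mobile, chest_ann, spans, config,
                           template_ann)
  ref_test <- truth_minute_durations(test$truth, spans, channel = "chest")

  # testing-session stages shared by both view variants
  filt_te <- bandpass_filter(test$mobile, low = config$low,
                             high = config$high, order = config$filter_order)
  st1 <- .detect_accept(filt_te, core$svm, config)
  segs_te <- segment_heartbeats(filt_te, st1$accepted)
  beats_te <- beat_set(filt_te, segs_te, length = config$resampled_len,
                       angle_gap = config$angle_gap)

  variant <- function(single_view) {
    if (single_view) {
      warps_tr <- .warp_all(core$beats, core$template, single_view = TRUE)
      ref_max <- max(warps_tr$distortion, na.rm = TRUE)
      pi_tr <- normalize_distortions(warps_tr$distortion, ref_max)
      tau <- triangle_threshold(pi_tr, nbins = config$nbins)$tau
    } else {
      warps_tr <- core$warps
      ref_max <- core$reference_max
      tau <- core$tau
    }
    q_tr <- .quality(warps_tr, ref_max, tau, config)
    warps_te <- .warp_all(beats_te, core$template, single_view = single_view)
    q_te <- .quality(warps_te, ref_max, tau, config)
    res <- list()
    for (use_sqi in c(FALSE, TRUE)) {
      sqi_tr <- if (use_sqi) q_tr$sqi else rep(1L, nrow(warps_tr))
      sqi_te <- if (use_sqi) q_te$sqi else rep(1L, nrow(warps_te))
      dur_tr <- beat_qrs_durations(core$segments, warps_tr, sqi_tr, core$fs,
                                   resampled_len = config$resampled_len,
                                   sanity_ms = config$sanity_ms)
      dur_te <- beat_qrs_durations(segs_te, warps_te, sqi_te, core$fs,
                                   resampled_len = config$resampled_len,
                                   sanity_ms = config$sanity_ms)
      min_tr <- minute_average(dur_tr, spans)$estimate_ms
      min_te <- minute_average(dur_te, spans)$estimate_ms
      bias <- fit_bias(min_tr, core$chest_minutes)
      for (use_cal in c(FALSE, TRUE)) {
        est <- if (use_cal) as.numeric(apply_calibration(min_te, bias)) else min_te
        m <- evaluate_estimates(est, ref_test)
        res[[length(res) + 1L]] <- data.frame(
          single_view = single_view, sqi = use_sqi, cal = use_cal,
          cr = m$cr, me = m$me, std = m$std, mae = m$mae, rmse = m$rmse)
      }
    }
    do.call(rbind, res)
  }

  tab <- rbind(variant(TRUE), variant(FALSE))
  # order rows: DTW, DTW+SQI, DTW+Cal, DTW+SQI+Cal, then the MV-DTW block
  tab <- tab[order(!tab$single_view, tab$sqi & tab$cal, tab$cal, tab$sqi), ]
  name <- function(r) paste0(if (r$single_view) "DTW" else "MV-DTW",
                             if (r$sqi) "+SQI" else "",
                             if (r$cal) "+Cal" else "")
  tab$approach <- vapply(seq_len(nrow(tab)), function(i) name(tab[i, ]),
                         character(1))
  rownames(tab) <- NULL
  tab[, c("approach", "cr", "me", "std", "mae", "rmse",
          "single_view", "sqi", "cal")]
}

#' Persist a fitted model as structured text (JSON)
#'
#' Stores every learned component — support vectors, weights, bias and
#' standardization constants of the SVM; the template views and boundary
#' indices; distortion normalization and threshold; calibration bias —
#' together with the configuration, at full precision.
#'
#' @param fit An `mqrs_fit`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_subject_model <- function(fit, path) {
  stopifnot(inherits(fit, "mqrs_fit"))
  payload <- list(
    package = "mobileqrs", format = 1L,
    subject_id = fit$subject_id, fs = fit$fs,
    svm = fit$svm[c("support_vectors", "alpha_y", "bias", "center",
                    "scale", "C")],
    template = list(views = fit$template$views,
                    qrs_temp_off = fit$template$qrs_temp_off,
                    qrs_temp_on = fit$template$qrs_temp_on,
                    length = fit$template$length,
                    beat_index = fit$template$beat_index,
                    cluster_share = fit$template$cluster_share,
                    segment = as.list(fit$template$segment)),
    reference_max = fit$reference_max, tau = fit$tau,
    bias_ms = fit$calibration$bias_ms,
    n_pairs = fit$calibration$n_pairs,
    config = unclass(fit$config), counts = as.list(fit$counts))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load a persisted subject model
#'
#' @param path Path written by [write_subject_model()].
#' @return An `mqrs_fit` (without the training-session intermediates).
#' @export
read_subject_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$package, "mobileqrs")) stop("not a mobileqrs model file")
  svm <- structure(list(
    support_vectors = as.matrix(p$svm$support_vectors),
    alpha_y = as.numeric(p$svm$alpha_y), bias = p$svm$bias,
    center = as.numeric(p$svm$center), scale = as.numeric(p$svm$scale),
    C = p$svm$C), class = "mqrs_svm")
  views <- as.matrix(p$template$views)
  rownames(views) <- c("amplitude", "derivative", "angle")[seq_len(nrow(views))]
  template <- structure(list(
    views = views, beat_index = p$template$beat_index,
    segment = as.data.frame(p$template$segment),
    length = p$template$length,
    cluster_share = p$template$cluster_share,
    qrs_temp_off = p$template$qrs_temp_off,
    qrs_temp_on = p$template$qrs_temp_on), class = "mqrs_template")
  cfg <- p$config
  cfg <- structure(cfg, class = "mqrs_config")
  structure(
    list(svm = svm, template = template, reference_max = p$reference_max,
         tau = p$tau,
         calibration = structure(list(bias_ms = p$bias_ms,
                                      n_pairs = p$n_pairs),
                                 class = "mqrs_calibration"),
         config = cfg, fs = p$fs, subject_id = p$subject_id,
         counts = unlist(p$counts), training = NULL),
    class = "mqrs_fit")
}
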