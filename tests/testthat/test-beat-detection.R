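# Construct a record with Gaussian spikes at the given times (s).
spike_record <- function(times, fs = 500, dur = NULL, amp = 1, sigma = 0.01,
                         baseline = 0) {
  if (is.null(dur)) dur <- max(times) + 1
  n <- round(dur * fs)
  tt <- (0:(n - 1)) / fs
  x <- rep(baseline, n)
  for (i in seq_along(times)) {
    a <- if (length(amp) > 1) amp[i] else amp
    x <- x + a * exp(-(tt - times[i])^2 / (2 * sigma^2))
  }
  ecg_record(x, fs = fs, role = "mobile")
}

test_that("isolated identical spikes are each detected at their apex", {
  times <- 0.5 + 0:9
  rec <- spike_record(times, dur = 11)
  cand <- detect_spike_candidates(rec)
  expect_length(cand, 10)
  expect_equal(cand, round(times * 500) + 1, tolerance = 1e-8)
})

test_that("the refractory rule keeps the larger of two close spikes", {
  rec <- spike_record(c(1.0, 1.1), dur = 3, amp = c(0.6, 1.0))
  cand <- detect_spike_candidates(rec, refractory_ms = 250)
  expect_length(cand, 1)
  expect_equal(cand, round(1.1 * 500) + 1)
  # with a short refractory both survive
  cand2 <- detect_spike_candidates(rec, refractory_ms = 40)
  expect_length(cand2, 2)
})

test_that("candidates cover true R peaks on clean generator output", {
  cfg <- synth_config(n_trials = 1, trial_minutes = 1, seed = 9,
                      artifact_len_s = 0, false_spike_rate = 0,
                      artifact_start_s = 0, eval_minute = 1)
  ses <- generate_session(cfg)
  filt <- bandpass_filter(ses$training$mobile)
  cand <- detect_spike_candidates(filt)
  truth <- ses$training$truth$beats$r_peak
  tol <- 0.020 * 500
  covered <- vapply(truth, function(r) any(abs(cand - r) <= tol), logical(1))
  expect_true(all(covered))
  expect_error(detect_spike_candidates(ecg_record(rnorm(100), fs = 500)),
               "shorter than one envelope window")
})

test_that("feature extraction produces the documented 10 features", {
  rec <- spike_record(2.0, dur = 4)
  p <- round(2.0 * 500) + 1
  X <- extract_features(rec, p)
  expect_equal(dim(X), c(1L, 10L))
  expect_true(all(is.finite(X)))
  expect_equal(unname(X[1, "f01"]), 1.0, tolerance = 1e-6) # apex amplitude
  expect_gt(X[1, "f10"], 0)                        # peaked window -> kurtosis
  # determinism: two candidates with identical surroundings
  rec2 <- spike_record(c(2, 6), dur = 8)
  X2 <- extract_features(rec2, round(c(2, 6) * 500) + 1)
  # features 1-6 and 10 are local and must match exactly
  expect_equal(X2[1, c(1:6, 10)], X2[2, c(1:6, 10)], tolerance = 1e-9)
})

test_that("half-max width matches a brute-force crossing scan on a rectangle", {
  fs <- 500
  for (w_ms in c(40, 80)) {
    n <- 2000
    x <- numeric(n)
    w <- round(w_ms / 1000 * fs)
    x[1000:(1000 + w - 1)] <- 1
    rec <- ecg_record(x, fs = fs)
    X <- extract_features(rec, 1000 + w %/% 2)
    expect_equal(unname(X[1, "f04"]), w / fs * 1000)
  }
})

test_that("labelling matches candidates one-to-one within tolerance", {
  ref <- ecg_annotations(r_peaks = c(1000, 2000, 3000))
  # exact hit, near pair competing for one reference, and an orphan
  cands <- c(1000, 1990, 2015, 3500)
  y <- label_candidates(cands, ref, fs = 500, tol_ms = 75)
  expect_equal(y, c(1L, 1L, -1L, -1L)) # 1990 is nearer to 2000 than 2015
  expect_error(label_candidates(cands, structure(list(r_peaks = integer(0)),
                                                 class = "ecg_annotations"),
                                fs = 500), "empty")
})

test_that("labels on generator output with false spikes match the truth table", {
  cfg <- synth_config(n_trials = 2, seed = 13, false_spike_rate = 6,
                      artifact_len_s = 0)
  ses <- generate_session(cfg)
  truth <- ses$training$truth
  filt <- bandpass_filter(ses$training$mobile)
  cand <- detect_spike_candidates(filt)
  y <- label_candidates(cand, truth_annotations(ses$training$chest_truth),
                        fs = 500)
  # candidates close to an injected false spike must be labelled -1,
  # those close to a true R peak +1
  near <- function(idx, set, tol) vapply(idx, function(i)
    length(set) > 0 && min(abs(set - i)) <= tol, logical(1))
  at_false <- near(cand, truth$false_spike_indices, 0.05 * 500)
  at_true <- near(cand, truth$beats$r_peak, 0.075 * 500)
  expect_true(all(y[at_false & !at_true] == -1L))
  expect_true(all(y[at_true] == 1L))
  expect_gt(sum(at_false & !at_true), 0) # some false spikes became candidates
})

test_that("the linear SVM separates a separable pair and ignores order", {
  set.seed(5)
  base <- matrix(rnorm(80), 8, 10)
  X <- base
  X[1:4, 3] <- X[1:4, 3] + 6
  y <- c(1, 1, 1, 1, -1, -1, -1, -1)
  m <- train_svm(X, y)
  expect_s3_class(m, "mqrs_svm")
  expect_equal(svm_predict(m, X), as.integer(y))
  # permuting the training order leaves predictions unchanged
  perm <- sample(8)
  m2 <- train_svm(X[perm, ], y[perm])
  set.seed(6)
  probe <- matrix(rnorm(200), 20, 10)
  expect_equal(svm_predict(m, probe), svm_predict(m2, probe))
  expect_error(train_svm(X, rep(1, 8)), "both classes")
})

test_that("decision values equal the explicit support-vector sum", {
  set.seed(7)
  X <- matrix(rnorm(120), 12, 10)
  y <- rep(c(1, -1), 6)
  X[y == 1, 1] <- X[y == 1, 1] + 2
  m <- train_svm(X, y)
  probe <- matrix(rnorm(50), 5, 10)
  d <- svm_decision(m, probe)
  # term-by-term recomputation of sum_i alpha_i y_i <x, x_i> + b
  oracle <- sapply(seq_len(5), function(r) {
    xs <- (probe[r, ] - m$center) / m$scale
    s <- m$bias
    for (i in seq_along(m$alpha_y)) {
      s <- s + m$alpha_y[i] * sum(xs * m$support_vectors[i, ])
    }
    s
  })
  expect_equal(d, oracle, tolerance = 1e-10)
})

test_that("decision values match a brute-force dual (SMO) solve on a toy set", {
  # 6 points, 2 features, non-separable so the box constraint is active
  X <- matrix(c(1.0, 1.2, 0.8, -1.0, -1.1, 0.9,
                0.9, 1.1, 1.3, -0.9, -1.2, -1.0), 6, 2)
  y <- c(1, 1, 1, -1, -1, -1)
  m <- train_svm(X, y, C = 1)
  d_pkg <- svm_decision(m, X)
  # oracle operates on the same standardized coordinates
  Xs <- sweep(sweep(X, 2, m$center), 2, m$scale, "/")
  o <- smo_linear_svc(Xs, y, C = 1)
  expect_equal(d_pkg, o$decision, tolerance = 5e-3)
})

test_that("sign(0) is defined as +1", {
  m <- structure(list(support_vectors = matrix(1, 1, 2), alpha_y = 1,
                      bias = 0, center = c(0, 0), scale = c(1, 1), C = 1),
                 class = "mqrs_svm")
  # x = x_1 gives k(x, x_1) = ||x_1||^2 >= 0 -> +1
  expect_equal(svm_predict(m, c(1, 1)), 1L)
  # decision exactly zero (x orthogonal to the support vector) -> +1
  expect_equal(svm_decision(m, c(1, -1)), 0)
  expect_equal(svm_predict(m, c(1, -1)), 1L)
  expect_error(svm_decision(m, c(1, 2, 3)), "dimension")
})

test_that("R-to-R segmentation tiles the peak range", {
  rec <- ecg_record(rnorm(2000), fs = 500)
  segs <- segment_heartbeats(rec, c(100, 600, 1100))
  expect_equal(segs$start, c(100, 600))
  expect_equal(segs$end, c(600, 1100))
  expect_error(segment_heartbeats(rec, 100), "at least 2")
  set.seed(8)
  peaks <- sort(sample(1500, 20))
  segs2 <- segment_heartbeats(rec, peaks)
  expect_equal(nrow(segs2), 19)
  expect_equal(segs2$end[-19], segs2$start[-1]) # no gaps, no overlaps
  expect_equal(sum(segs2$length), max(peaks) - min(peaks))
})
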