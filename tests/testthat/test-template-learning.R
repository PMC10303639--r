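# Small synthetic beat matrices (rows = beats) for clustering tests.
make_groups <- function(centers, per_group = 5, spread = 0.05, dim = 12,
                        seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(centers, function(c0)
    t(replicate(per_group, c0 + rnorm(dim, 0, spread)))))
}

test_that("K-means++ seeding follows the distance-proportional law", {
  # base case: K = 1 is a uniform draw
  X <- matrix(c(0, 1, 2, 10), 4, 1)
  set.seed(1)
  s <- replicate(2000, kmeanspp_seed(X, 1))
  expect_gt(min(table(factor(s, levels = 1:4))), 2000 / 4 * 0.7)

  # a beat identical to a chosen seed is never selected as the next seed
  Xd <- matrix(c(0, 0, 5), 3, 1)
  set.seed(2)
  for (i in 1:200) {
    s2 <- kmeanspp_seed(Xd, 2)
    if (s2[1] %in% c(1, 2)) {
      expect_false(setdiff(s2, s2[1]) == setdiff(c(1, 2), s2[1]) &&
                     s2[2] != 3)
      expect_equal(s2[2], 3)
    }
  }
  expect_error(kmeanspp_seed(X, 5), "K")
})

test_that("empirical second-seed frequencies match the exact probabilities", {
  # 4 beats on a line; first seed forced by conditioning on draws where it
  # is beat 1; second-seed law: w proportional to distance to beat 1
  X <- matrix(c(0, 1, 3, 7), 4, 1)
  set.seed(3)
  draws <- replicate(20000, kmeanspp_seed(X, 2))
  sel <- draws[, draws[1, ] == 1]
  n <- ncol(sel)
  p_true <- c(0, 1, 3, 7) / sum(c(0, 1, 3, 7))
  for (b in 2:4) {
    phat <- mean(sel[2, ] == b)
    se <- sqrt(p_true[b] * (1 - p_true[b]) / n)
    expect_lt(abs(phat - p_true[b]), 3 * se + 1e-12)
  }
  expect_equal(sum(sel[2, ] == 1), 0) # zero-distance beat never chosen
})

test_that("PAM finds the exact optimum on well-separated groups", {
  X <- make_groups(list(rep(0, 12), rep(1, 12), rep(3, 12)))
  set.seed(4)
  seeds <- kmeanspp_seed(X, 3)
  cl <- pam_cluster(X, seeds)
  # one medoid per group
  expect_equal(sort((cl$medoids - 1) %/% 5), 0:2)
  # equals the brute-force minimum over all medoid triples
  combs <- combn(15, 3)
  best <- min(apply(combs, 2, function(m) naive_xi(X, m)))
  expect_equal(cl$objective, best, tolerance = 1e-6)
  # objective strictly decreases across accepted swaps
  expect_true(all(diff(cl$trace) < 0) || length(cl$trace) == 1)
})

test_that("PAM on identical beats reaches a zero objective", {
  X <- matrix(1, 6, 4)
  cl <- pam_cluster(X, c(1, 2))
  expect_equal(cl$objective, 0)
})

test_that("PAM agrees with an independent implementation on random data", {
  skip_if_not_installed("cluster")
  set.seed(5)
  X <- matrix(rnorm(40 * 6), 40, 6)
  seeds <- kmeanspp_seed(X, 3)
  cl <- pam_cluster(X, seeds)
  ref <- cluster::pam(X, k = 3, metric = "euclidean", do.swap = TRUE)
  # both are swap-descent local optima of the same objective; ours started
  # from k-means++ seeds so require agreement within a small relative gap
  xi_ref <- sum(ref$clustering |> (\(a) sapply(seq_len(40), function(i)
    sqrt(sum((X[i, ] - ref$medoids[a[i], ])^2))))())
  expect_lt(abs(cl$objective - xi_ref) / xi_ref, 0.02)
})

test_that("template selection picks the largest cluster with fixed tie-breaks", {
  X <- make_groups(list(rep(0, 12), rep(1, 12), rep(3, 12)),
                   per_group = 3, seed = 6)
  # graft extra members onto group 2 to make it largest
  X <- rbind(X, matrix(1 + rnorm(7 * 12, 0, 0.05), 7, 12))
  bs <- structure(list(views = rep(list(matrix(0, 3, 4)), nrow(X)),
                       concat = X, degenerate = rep(FALSE, nrow(X)),
                       segments = data.frame(start = seq_len(nrow(X)),
                                             end = seq_len(nrow(X)) + 100,
                                             length = 100),
                       length = 4),
                  class = "mqrs_beatset")
  set.seed(7)
  cl <- pam_cluster(X, kmeanspp_seed(X, 3))
  tm <- select_template(cl, bs)
  sizes <- table(cl$assignment)
  expect_equal(sum(cl$assignment == tm$beat_index), max(sizes))
  # deterministic under ties: two singleton clusters, tie broken by index
  X2 <- matrix(c(0, 10), 2, 1)
  cl2 <- pam_cluster(X2, c(1, 2))
  bs2 <- structure(list(views = list(matrix(0, 3, 2), matrix(0, 3, 2)),
                        concat = X2, degenerate = c(FALSE, FALSE),
                        segments = data.frame(start = c(1, 2),
                                              end = c(101, 102),
                                              length = 100),
                        length = 2),
                   class = "mqrs_beatset")
  expect_equal(select_template(cl2, bs2)$beat_index, 1L)
})

test_that("template boundary annotation maps through the resampling ratio", {
  ses <- small_session()
  filt <- bandpass_filter(ses$training$mobile)
  truth <- ses$training$truth
  peaks <- truth$beats$r_peak[10:13]
  segs <- segment_heartbeats(filt, peaks)
  bs <- beat_set(filt, segs, length = 512)
  cl <- pam_cluster(bs$concat, c(1, 2))
  tm <- select_template(cl, bs)
  ann <- truth_annotations(truth)
  tm2 <- annotate_template_boundaries(tm, reference = ann, fs = 500)
  j <- which(truth$beats$r_peak == tm2$segment$start)
  ratio <- (512 - 1) / (tm2$segment$length - 1)
  expect_equal(tm2$qrs_temp_off,
               round(1 + (truth$beats$qrs_off[j] - tm2$segment$start) * ratio))
  expect_equal(tm2$qrs_temp_on,
               round(1 + (truth$beats$qrs_on[j + 1] - tm2$segment$start) * ratio))
  expect_true(tm2$qrs_temp_off < tm2$qrs_temp_on)

  # doubling the template length doubles the mapped boundary offsets
  tm_long <- tm
  tm_long$length <- 1023 # so that (len-1) ratio exactly doubles
  tm_long$views <- matrix(0, 3, 1023)
  tm3 <- annotate_template_boundaries(tm_long, reference = ann, fs = 500)
  expect_equal(tm3$qrs_temp_off - 1, 2 * (tm2$qrs_temp_off - 1),
               tolerance = 0.51 / (tm2$qrs_temp_off - 1)) # rounding slack
  # boundary outside the segment errors
  expect_error(annotate_template_boundaries(tm, qrs_off = tm$segment$end + 10,
                                            qrs_on = tm$segment$end + 20),
               "outside")
})

test_that("degenerate beats are excluded from template learning", {
  ses <- small_session()
  filt <- bandpass_filter(ses$training$mobile)
  truth <- ses$training$truth
  peaks <- truth$beats$r_peak[5:15]
  segs <- segment_heartbeats(filt, peaks)
  bs <- beat_set(filt, segs, length = 512)
  bs$degenerate[3] <- TRUE
  set.seed(8)
  tm <- learn_template(bs, K = 3)
  expect_false(tm$beat_index == 3)
  cl <- attr(tm, "clustering")
  expect_false(3 %in% cl$medoids)
})
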