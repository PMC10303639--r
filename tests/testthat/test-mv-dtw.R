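# A smooth synthetic beat shape on [0, 1] for view/warp tests.
toy_beat <- function(M = 64) {
  tt <- seq(0, 1, length.out = M)
  as.numeric(minmax_scale(exp(-(tt - 0.15)^2 / 0.002) +
                            0.4 * exp(-(tt - 0.7)^2 / 0.01)))
}

toy_template <- function(M = 64, off = 12, on = 55) {
  v <- build_views(toy_beat(M))
  structure(list(views = v, beat_index = 1L,
                 segment = data.frame(start = 1, end = M + 1, length = M),
                 length = M, cluster_share = 1,
                 qrs_temp_off = off, qrs_temp_on = on),
            class = "mqrs_template")
}

test_that("view construction: derivative, angle, scaling, degeneracy", {
  # straight line (exactly representable): derivative and angle constant
  # -> both views flat
  line <- (0:49) * 0.5
  v <- build_views(line, angle_gap = 5)
  expect_equal(dim(v), c(3L, 50L))
  expect_true(all(v["derivative", ] == 0)) # constant view scales to zeros
  expect_true(all(v["angle", ] == 0))
  expect_false(attr(v, "degenerate"))

  # symmetric triangle: the angle view is minimal at the apex
  tri <- c(seq(0, 1, length.out = 26), seq(1, 0, length.out = 26)[-1])
  vt <- build_views(tri, angle_gap = 5)
  expect_equal(which.min(vt["angle", ]), 26L)

  # interior angles equal a direct two-vector arccos computation
  set.seed(9)
  x <- cumsum(rnorm(60, 0, 0.1))
  x <- as.numeric(minmax_scale(x))
  g <- 10
  vv <- build_views(x, angle_gap = g)
  raw_ang <- sapply((g + 1):(60 - g), function(i) direct_angle(x, i, g))
  scaled <- (raw_ang - min(range_pad <- c(rep(raw_ang[1], g), raw_ang,
                                          rep(raw_ang[length(raw_ang)], g)))) /
    diff(range(range_pad))
  expect_equal(vv["angle", (g + 1):(60 - g)], scaled, tolerance = 1e-12)

  expect_error(build_views(x[1:15], angle_gap = 10), "too short")
  flat <- build_views(rep(0.5, 50), angle_gap = 5)
  expect_true(attr(flat, "degenerate"))
})

test_that("local distance is the squared Euclidean across views", {
  tm <- toy_template()
  d <- local_distance(tm$views, tm)
  expect_equal(diag(d), rep(0, 64))
  expect_true(all(d >= 0))
  # printed single-view example
  d2 <- local_distance(matrix(c(0, 1), 1), matrix(c(0, 1, 1), 1))
  expect_equal(d2, rbind(c(0, 1, 1), c(1, 0, 0)))
  # random instance vs elementwise brute force
  set.seed(10)
  A <- matrix(runif(15), 3, 5)
  B <- matrix(runif(21), 3, 7)
  d3 <- local_distance(A, B)
  for (m in 1:5) for (n in 1:7) {
    expect_equal(d3[m, n], sum((A[, m] - B[, n])^2), tolerance = 1e-14)
  }
  expect_error(local_distance(A, matrix(0, 2, 4)), "views")
})

test_that("the path table matches hand and exhaustive dynamic programming", {
  # identical sequences: diagonal path, zero terminal distance
  tm <- toy_template()
  tab <- path_table(local_distance(tm$views, tm))
  expect_equal(distortion(tab), 0)
  expect_equal(tab$path, cbind(1:64, 1:64))

  # hand-checked instance
  tab2 <- path_table(rbind(c(0, 1, 1), c(1, 0, 0)))
  expect_equal(tab2$D[2, 3], 0)

  # exhaustive oracle on random small instances
  set.seed(11)
  for (i in 1:120) {
    M <- sample(2:8, 1); N <- sample(2:8, 1)
    d <- matrix(runif(M * N), M, N)
    tab3 <- path_table(d)
    expect_equal(distortion(tab3), enum_dtw_min(d), tolerance = 1e-12)
    # terminal distance equals the path sum
    expect_equal(distortion(tab3), sum(d[tab3$path]), tolerance = 1e-12)
    # monotone steps only
    steps <- diff(tab3$path)
    expect_true(all(steps >= 0) && all(rowSums(steps) >= 1))
  }
})

test_that("terminal cost is symmetric under swapping test and template", {
  set.seed(12)
  A <- matrix(runif(24), 3, 8)
  B <- matrix(runif(18), 3, 6)
  dab <- local_distance(A, B)
  dba <- local_distance(B, A)
  expect_equal(dba, t(dab))
  expect_equal(distortion(path_table(dab)), distortion(path_table(dba)))
})

test_that("boundary transfer: identity, stretch, and ordering invariant", {
  tm <- toy_template()
  w <- mv_dtw(tm$views, tm)
  expect_equal(w$qrs_off, tm$qrs_temp_off)
  expect_equal(w$qrs_on, tm$qrs_temp_on)
  expect_equal(w$distortion, 0)

  # test = template stretched x2 by sample repetition
  stretched <- tm$views[, rep(1:64, each = 2)]
  w2 <- mv_dtw(stretched, tm)
  expect_lte(abs(w2$qrs_off - 2 * tm$qrs_temp_off), 1)
  expect_lte(abs(w2$qrs_on - 2 * tm$qrs_temp_on), 1)
  expect_lt(w2$qrs_off, w2$qrs_on)

  # located boundaries on a noisy copy stay near the template's
  set.seed(13)
  for (i in 1:20) {
    noisy <- apply(tm$views + matrix(rnorm(3 * 64, 0, 0.03), 3), 2,
                   function(z) pmin(pmax(z, 0), 1))
    wn <- mv_dtw(noisy, tm)
    expect_lt(wn$qrs_off, wn$qrs_on)
    expect_lte(abs(wn$qrs_off - tm$qrs_temp_off), 4)
    expect_lte(abs(wn$qrs_on - tm$qrs_temp_on), 4)
  }
  expect_error(locate_qrs(path_table(matrix(0, 3, 3)),
                          list(qrs_temp_off = 1, qrs_temp_on = 5)),
               "outside")
})

test_that("distortion is nondecreasing in injected noise amplitude", {
  tm <- toy_template()
  meds <- sapply(c(0.01, 0.05, 0.15), function(s) {
    set.seed(14)
    median(replicate(100, {
      noisy <- pmin(pmax(tm$views + matrix(rnorm(3 * 64, 0, s), 3), 0), 1)
      mv_dtw(noisy, tm)$distortion
    }))
  })
  expect_true(all(diff(meds) > 0))
})

test_that("single-view warping uses only the amplitude view", {
  tm <- toy_template()
  other <- tm$views
  other["angle", ] <- rev(other["angle", ]) # corrupt a non-amplitude view
  w <- mv_dtw(other, tm, single_view = TRUE)
  expect_equal(w$distortion, 0)
  w3 <- mv_dtw(other, tm, single_view = FALSE)
  expect_gt(w3$distortion, 0)
})
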