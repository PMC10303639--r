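# Independent reference implementations used as test oracles. These stay
# deliberately naive (loops, recursion, from-scratch objectives) so they
# share no code path with the package.

# Minimum cost over all monotone warping paths of a local-distance matrix,
# by recursive enumeration from cell (m, n) to the terminal cell (no
# memoization, no table).
enum_dtw_min <- function(d) {
  M <- nrow(d); N <- ncol(d)
  rec <- function(m, n) {
    if (m == M && n == N) return(d[m, n])
    best <- Inf
    if (m < M) best <- min(best, rec(m + 1, n))
    if (n < N) best <- min(best, rec(m, n + 1))
    if (m < M && n < N) best <- min(best, rec(m + 1, n + 1))
    d[m, n] + best
  }
  rec(1, 1)
}

# From-scratch K-medoid objective: summed Euclidean distance of every row
# to its nearest medoid row.
naive_xi <- function(X, medoids) {
  tot <- 0
  for (i in seq_len(nrow(X))) {
    dmin <- Inf
    for (m in medoids) {
      dd <- sqrt(sum((X[i, ] - X[m, ])^2))
      if (dd < dmin) dmin <- dd
    }
    tot <- tot + dmin
  }
  tot
}

# Best-improvement single-swap descent over medoid sets, recomputing the
# objective from scratch for every candidate swap.
naive_pam_descent <- function(X, seeds) {
  medoids <- sort(as.integer(seeds))
  cur <- naive_xi(X, medoids)
  repeat {
    best <- cur
    best_set <- NULL
    for (k in seq_along(medoids)) {
      for (c in setdiff(seq_len(nrow(X)), medoids)) {
        trial <- medoids
        trial[k] <- c
        val <- naive_xi(X, trial)
        if (val < best - 1e-12) {
          best <- val
          best_set <- sort(trial)
        }
      }
    }
    if (is.null(best_set)) break
    medoids <- best_set
    cur <- best
  }
  list(medoids = medoids, objective = cur)
}

# Tiny SMO-style solver for the soft-margin linear SVC dual:
#   max sum(a) - 0.5 * sum_ij a_i a_j y_i y_j <x_i, x_j>
#   s.t. 0 <= a_i <= C, sum a_i y_i = 0.
# Pairwise analytic updates swept until convergence; fine for toy sizes.
smo_linear_svc <- function(X, y, C = 1, iters = 5000, tol = 1e-10) {
  n <- nrow(X)
  K <- X %*% t(X)
  a <- rep(0, n)
  f <- function() as.numeric(K %*% (a * y)) # decision without bias
  for (it in seq_len(iters)) {
    changed <- FALSE
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        g <- f()
        # optimal step for the pair (i, j) along the constraint manifold
        eta <- K[i, i] + K[j, j] - 2 * K[i, j]
        if (eta <= 0) next
        # gradient of dual wrt a_i moving with da_j = -y_i y_j da_i
        grad <- (1 - y[i] * g[i]) - y[i] * y[j] * (1 - y[j] * g[j])
        da <- grad / eta
        lo <- max(-a[i], if (y[i] * y[j] > 0) a[j] - C else -a[j])
        hi <- min(C - a[i], if (y[i] * y[j] > 0) a[j] else C - a[j])
        da <- min(max(da, lo), hi)
        if (abs(da) > tol) {
          a[i] <- a[i] + da
          a[j] <- a[j] - y[i] * y[j] * da
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  g <- f()
  sv <- which(a > 1e-8 & a < C - 1e-8)
  b <- if (length(sv) > 0) mean(y[sv] - g[sv]) else {
    # fall back to midpoint of the feasible bias interval
    up <- min((y - g)[y == +1])
    dn <- max((y - g)[y == -1])
    (up + dn) / 2
  }
  list(alpha = a, b = b, decision = g + b)
}

# Direct two-vector angle at index i with gap g, in coordinates where g
# index steps span one unit.
direct_angle <- function(x, i, g) {
  a <- c(-1, x[i - g] - x[i])
  b <- c(1, x[i + g] - x[i])
  acos(max(-1, min(1, sum(a * b) / sqrt(sum(a^2) * sum(b^2)))))
}
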