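#' Assemble a beat set for clustering
#'
#' Resamples each R-to-R segment to a common length, min-max scales it,
#' expands it to the three views, and concatenates the views into one
#' feature vector per beat (Euclidean distance on this concatenation is
#' the clustering metric). Flat-line (degenerate) segments are kept in the
#' set but flagged; clustering and warping exclude them.
#'
#' @param rec A filtered [ecg_record()].
#' @param segments Segment table from [segment_heartbeats()].
#' @param length Common resampled beat length.
#' @param angle_gap Angle-view neighbour distance (samples), see
#'   [build_views()].
#' @return An object of class `mqrs_beatset`: list with `views` (list of
#'   3 x `length` matrices), `concat` (beats x 3*`length` matrix),
#'   `degenerate` (logical), `segments`, `length`.
#' @export
beat_set <- function(rec, segments, length = 256, angle_gap = 10) {
  stopifnot(inherits(rec, "ecg_record"))
  n <- nrow(segments)
  views <- vector("list", n)
  degenerate <- logical(n)
  concat <- matrix(0, n, 3L * length)
  for (j in seq_len(n)) {
    raw <- rec$samples[segments$start[j]:(segments$end[j] - 1L)]
    res <- resample_to_length(raw, length)
    sc <- minmax_scale(res)
    if (isTRUE(attr(sc, "degenerate"))) {
      degenerate[j] <- TRUE
      views[[j]] <- matrix(0, 3L, length,
                           dimnames = list(c("amplitude", "derivative", "angle"), NULL))
    } else {
      v <- build_views(as.numeric(sc), angle_gap = angle_gap)
      degenerate[j] <- isTRUE(attr(v, "degenerate"))
      views[[j]] <- v
    }
    concat[j, ] <- as.numeric(t(views[[j]]))
  }
  structure(list(views = views, concat = concat, degenerate = degenerate,
                 segments = segments, length = length),
            class = "mqrs_beatset")
}

#' @export
print.mqrs_beatset <- function(x, ...) {
  cat(sprintf("<mqrs_beatset: %d beats of length %d (%d degenerate)>\n",
              length(x$views), x$length, sum(x$degenerate)))
  invisible(x)
}

.pairwise_dist <- function(X) {
  # full-precision Euclidean distances (no crossprod identity, which can
  # lose enough precision to flip near-tied swap decisions)
  unname(as.matrix(stats::dist(X)))
}

#' K-means++ seeding for K-medoid clustering
#'
#' Draws the first seed uniformly at random; each subsequent seed is drawn
#' with probability proportional to its Euclidean distance to the closest
#' already-chosen seed (so a beat identical to a chosen seed has selection
#' probability zero). Uses R's RNG: set a seed beforehand for
#' reproducibility.
#'
#' @param X Beats x features matrix (e.g. `beat_set(...)$concat`), or an
#'   `mqrs_beatset`.
#' @param K Number of seeds.
#' @return Integer vector of K distinct row indices.
#' @export
kmeanspp_seed <- function(X, K = 3) {
  if (inherits(X, "mqrs_beatset")) X <- X$concat
  X <- as.matrix(X)
  n <- nrow(X)
  if (K < 1L || K > n) stop("need 1 <= K <= number of beats")
  seeds <- integer(K)
  seeds[1] <- sample.int(n, 1L)
  if (K > 1L) {
    dmin <- sqrt(rowSums(sweep(X, 2, X[seeds[1], ])^2))
    for (j in 2:K) {
      w <- dmin
      w[seeds[seq_len(j - 1L)]] <- 0
      if (sum(w) <= 0) {
        # all remaining beats coincide with chosen seeds; fall back to uniform
        pool <- setdiff(seq_len(n), seeds[seq_len(j - 1L)])
        seeds[j] <- if (length(pool) == 1L) pool else sample(pool, 1L)
      } else {
        seeds[j] <- sample.int(n, 1L, prob = w / sum(w))
      }
      dnew <- sqrt(rowSums(sweep(X, 2, X[seeds[j], ])^2))
      dmin <- pmin(dmin, dnew)
    }
  }
  seeds
}

#' K-medoid clustering by partitioning around medoids (PAM)
#'
#' Best-improvement swap descent: starting from the seed medoids, every
#' (medoid, non-medoid) swap is evaluated and the swap giving the largest
#' reduction of the summed instance-to-nearest-medoid Euclidean
#' dissimilarity is applied, until no swap improves. The objective is
#' therefore strictly decreasing across accepted swaps and the result is a
#' local optimum of the full swap neighbourhood.
#'
#' @param X Beats x features matrix or an `mqrs_beatset`.
#' @param seeds Initial medoid row indices (e.g. from [kmeanspp_seed()]).
#' @return An object of class `mqrs_clustering`: list with `medoids`
#'   (indices), `assignment` (nearest medoid index per beat), `objective`,
#'   and `trace` (objective after seeding and after each accepted swap).
#' @export
pam_cluster <- function(X, seeds) {
  if (inherits(X, "mqrs_beatset")) X <- X$concat
  X <- as.matrix(X)
  n <- nrow(X)
  seeds <- as.integer(seeds)
  if (anyDuplicated(seeds) || any(seeds < 1L | seeds > n))
    stop("'seeds' must be distinct row indices")
  D <- .pairwise_dist(X)
  medoids <- sort(seeds)
  K <- length(medoids)
  obj <- function(meds) sum(apply(D[, meds, drop = FALSE], 1L, min))
  cur <- obj(medoids)
  trace <- cur
  repeat {
    best_gain <- 0
    best_swap <- NULL
    nonmed <- setdiff(seq_len(n), medoids)
    if (length(nonmed) == 0L) break
    for (k in seq_len(K)) {
      others <- medoids[-k]
      dmin_others <- if (K > 1L)
        apply(D[, others, drop = FALSE], 1L, min) else rep(Inf, n)
      # candidate costs, vectorized over all non-medoids
      costs <- colSums(pmin(D[, nonmed, drop = FALSE], dmin_others))
      gains <- cur - costs
      i <- which.max(gains)
      if (gains[i] > best_gain + 1e-12) {
        best_gain <- gains[i]
        best_swap <- c(k, nonmed[i])
      }
    }
    if (is.null(best_swap)) break
    medoids[best_swap[1]] <- best_swap[2]
    medoids <- sort(medoids)
    cur <- cur - best_gain
    trace <- c(trace, cur)
  }
  assignment <- medoids[apply(D[, medoids, drop = FALSE], 1L, which.min)]
  assignment[medoids] <- medoids # each medoid belongs to itself
  structure(list(medoids = medoids, assignment = assignment,
                 objective = cur, trace = trace),
            class = "mqrs_clustering")
}

#' @export
print.mqrs_clustering <- function(x, ...) {
  sizes <- table(factor(x$assignment, levels = x$medoids))
  cat(sprintf("<mqrs_clustering: K = %d, objective = %.6g, cluster sizes: %s>\n",
              length(x$medoids), x$objective,
              paste(as.integer(sizes), collapse = "/")))
  invisible(x)
}

#' Select the heartbeat template from a clustering
#'
#' The template is the medoid of the most-populous cluster — the beat that
#' represents the largest share of the subject's training beats. Ties are
#' broken by the lower within-cluster dissimilarity sum, then by the lower
#' medoid index. QRS boundaries are unset until
#' [annotate_template_boundaries()] is called.
#'
#' @param clustering An `mqrs_clustering`.
#' @param beats The `mqrs_beatset` the clustering was computed on.
#' @return An object of class `mqrs_template`: list with `views` (3 x N),
#'   `beat_index` (row in the beat set), `segment` (start/end/length in
#'   record samples), `cluster_share`, and unset `qrs_temp_off`,
#'   `qrs_temp_on`.
#' @export
select_template <- function(clustering, beats) {
  stopifnot(inherits(clustering, "mqrs_clustering"),
            inherits(beats, "mqrs_beatset"))
  meds <- clustering$medoids
  sizes <- vapply(meds, function(m) sum(clustering$assignment == m), integer(1))
  X <- beats$concat
  wss <- vapply(meds, function(m) {
    members <- which(clustering$assignment == m)
    sum(sqrt(rowSums(sweep(X[members, , drop = FALSE], 2, X[m, ])^2)))
  }, numeric(1))
  ord <- order(-sizes, wss, meds)
  chosen <- meds[ord[1]]
  structure(
    list(views = beats$views[[chosen]], beat_index = chosen,
         segment = beats$segments[chosen, , drop = FALSE],
         length = beats$length,
         cluster_share = sizes[ord[1]] / nrow(beats$concat),
         qrs_temp_off = NULL, qrs_temp_on = NULL),
    class = "mqrs_template"
  )
}

#' @export
print.mqrs_template <- function(x, ...) {
  ann <- if (is.null(x$qrs_temp_off)) "boundaries unset"
         else sprintf("qrs_temp_off = %d, qrs_temp_on = %d",
                      x$qrs_temp_off, x$qrs_temp_on)
  cat(sprintf("<mqrs_template: length %d, cluster share %.0f%%, %s>\n",
              x$length, 100 * x$cluster_share, ann))
  invisible(x)
}

#' Annotate template QRS boundaries
#'
#' Attaches the template's QRS-offset (of the beat at the segment start)
#' and next-beat QRS-onset indices, in template sample coordinates. The
#' boundaries can be given directly (`qrs_off`/`qrs_on`, record sample
#' indices inside the template's source segment), or looked up from a
#' time-aligned reference annotation track with per-beat QRS boundaries —
#' typically the synchronized chest-lead annotations: the reference beat
#' whose R peak is nearest the segment start contributes its offset, the
#' following reference beat its onset. Record coordinates are mapped into
#' template coordinates through the resampling ratio.
#'
#' @param template An `mqrs_template` from [select_template()].
#' @param reference Optional [ecg_annotations()] with `qrs_on`/`qrs_off`.
#' @param qrs_off,qrs_on Optional explicit record sample indices.
#' @param tol_ms R-peak matching tolerance when `reference` is used.
#' @param fs Sampling rate (Hz), required with `reference`.
#' @return The template with `qrs_temp_off` and `qrs_temp_on` set.
#' @export
annotate_template_boundaries <- function(template, reference = NULL,
                                         qrs_off = NULL, qrs_on = NULL,
                                         tol_ms = 100, fs = NULL) {
  stopifnot(inherits(template, "mqrs_template"))
  seg <- template$segment
  if (!is.null(reference)) {
    stopifnot(inherits(reference, "ecg_annotations"))
    if (is.null(reference$qrs_on))
      stop("reference annotations carry no QRS boundaries")
    if (is.null(fs)) stop("'fs' is required to match reference beats")
    tol <- tol_ms / 1000 * fs
    j1 <- which.min(abs(reference$r_peaks - seg$start))
    j2 <- which.min(abs(reference$r_peaks - seg$end))
    if (abs(reference$r_peaks[j1] - seg$start) > tol ||
        abs(reference$r_peaks[j2] - seg$end) > tol || j2 != j1 + 1L)
      stop("no reference beat pair matches the template's source segment")
    qrs_off <- reference$qrs_off[j1]
    qrs_on <- reference$qrs_on[j2]
  }
  if (is.null(qrs_off) || is.null(qrs_on))
    stop("supply either 'reference' or both 'qrs_off' and 'qrs_on'")
  if (qrs_off <= seg$start || qrs_on >= seg$end || qrs_off >= qrs_on)
    stop("QRS boundaries fall outside the template's source segment")
  ratio <- (template$length - 1) / (seg$length - 1)
  template$qrs_temp_off <- as.integer(round(1 + (qrs_off - seg$start) * ratio))
  template$qrs_temp_on <- as.integer(round(1 + (qrs_on - seg$start) * ratio))
  template$qrs_temp_off <- max(2L, template$qrs_temp_off)
  template$qrs_temp_on <- min(template$length, template$qrs_temp_on)
  if (template$qrs_temp_off >= template$qrs_temp_on)
    stop("template boundaries collapsed after resampling")
  template
}

#' Learn the per-subject heartbeat template
#'
#' One-call wrapper: K-means++ seeding, PAM clustering, and selection of
#' the medoid of the largest cluster. Degenerate (flat) beats are excluded
#' from clustering.
#'
#' @param beats An `mqrs_beatset`.
#' @param K Number of clusters.
#' @return An unannotated `mqrs_template` (with the clustering attached as
#'   attribute `clustering`).
#' @export
learn_template <- function(beats, K = 3) {
  stopifnot(inherits(beats, "mqrs_beatset"))
  keep <- which(!beats$degenerate)
  if (length(keep) < K) stop("fewer usable beats than clusters")
  Xk <- beats$concat[keep, , drop = FALSE]
  seeds <- kmeanspp_seed(Xk, K)
  cl <- pam_cluster(Xk, seeds)
  # map back to full beat-set indexing
  cl$medoids <- keep[cl$medoids]
  cl$assignment <- keep[cl$assignment]
  tmpl_sub <- select_template(
    structure(list(medoids = match(cl$medoids, keep),
                   assignment = match(cl$assignment, keep),
                   objective = cl$objective, trace = cl$trace),
              class = "mqrs_clustering"),
    structure(list(views = beats$views[keep], concat = Xk,
                   degenerate = rep(FALSE, length(keep)),
                   segments = beats$segments[keep, , drop = FALSE],
                   length = beats$length),
              class = "mqrs_beatset"))
  tmpl_sub$beat_index <- keep[tmpl_sub$beat_index]
  attr(tmpl_sub, "clustering") <- cl
  tmpl_sub
}
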