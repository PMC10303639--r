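#' Expand a scaled heartbeat into its three-view representation
#'
#' Builds the multiview representation used for template clustering and
#' dynamic time warping: the amplitude series itself, its first difference
#' (last difference repeated so the view keeps the beat length), and the
#' local-angle series — the interior angle at each vertex `(i, x[i])`
#' formed with the neighbours `g` samples away on either side, computed in
#' normalized coordinates where `g` index steps span one unit, so the angle
#' reflects piece-wise fluctuations rather than the sampling rate. Edge
#' positions without both neighbours take the nearest valid angle. Each
#' view is min-max scaled to `[0, 1]`.
#'
#' @param beat Numeric amplitude sequence (a scaled R-to-R beat).
#' @param angle_gap Neighbour distance `g` for the angle view (samples).
#' @return A 3 x M matrix with rows `amplitude`, `derivative`, `angle`,
#'   each in `[0, 1]`, with a logical `degenerate` attribute (flat input).
#' @export
build_views <- function(beat, angle_gap = 10) {
  beat <- as.numeric(beat)
  M <- length(beat)
  if (M <= 2L * angle_gap)
    stop("beat too short for angle_gap = ", angle_gap)
  g <- as.integer(angle_gap)

  amp <- minmax_scale(beat)
  degenerate <- isTRUE(attr(amp, "degenerate"))

  dv <- diff(beat)
  dv <- c(dv, dv[length(dv)])

  idx <- (g + 1L):(M - g)
  # vectors to the two neighbours, index axis scaled so g steps = 1 unit
  dy1 <- beat[idx - g] - beat[idx]
  dy2 <- beat[idx + g] - beat[idx]
  cosang <- (-1 + dy1 * dy2) / (sqrt(1 + dy1^2) * sqrt(1 + dy2^2))
  ang_core <- acos(pmin(1, pmax(-1, cosang)))
  ang <- c(rep(ang_core[1], g), ang_core, rep(ang_core[length(ang_core)], g))

  scale0 <- function(v) {
    s <- minmax_scale(v)
    attributes(s) <- NULL
    s
  }
  out <- rbind(amplitude = scale0(amp), derivative = scale0(dv),
               angle = scale0(ang))
  attr(out, "degenerate") <- degenerate
  out
}

#' Multiview local distance matrix
#'
#' `d[m, n]` is the squared Euclidean distance across the L views between
#' sample `m` of the test beat and sample `n` of the template (sum of
#' squared per-view differences, no square root).
#'
#' @param test,template View matrices (L x M and L x N, rows = views), as
#'   produced by [build_views()]; a template object from
#'   [select_template()]/[annotate_template_boundaries()] is also accepted.
#' @return An M x N nonnegative matrix.
#' @export
local_distance <- function(test, template) {
  if (inherits(template, "mqrs_template")) template <- template$views
  test <- as.matrix(test); template <- as.matrix(template)
  if (nrow(test) != nrow(template))
    stop("test and template must have the same number of views")
  cpp_local_distance(test, template)
}

#' DTW path-distance table and optimal warping path
#'
#' Fills the accumulated table by dynamic programming — each cell adds its
#' local distance to the minimum of the three preceding neighbours
#' `(m-1, n)`, `(m-1, n-1)`, `(m, n-1)` — and backtracks the optimal
#' monotone path from the terminal cell (ties broken diagonal first, then
#' `(m-1, n)`, then `(m, n-1)`). No global band constraint is applied.
#'
#' @param d Local distance matrix from [local_distance()].
#' @return An object of class `mqrs_path_table`: list with the local
#'   matrix `d`, accumulated table `D`, and `path` (K x 2 matrix of
#'   1-based `(m, n)` pairs from `(1, 1)` to `(M, N)`).
#' @export
path_table <- function(d) {
  d <- as.matrix(d)
  if (length(d) == 0L) stop("empty local distance matrix")
  res <- cpp_dtw_table(d)
  structure(list(d = d, D = res$D, path = res$path),
            class = "mqrs_path_table")
}

#' @export
print.mqrs_path_table <- function(x, ...) {
  cat(sprintf("<mqrs_path_table: %d x %d, terminal distance %.6g, path length %d>\n",
              nrow(x$D), ncol(x$D), x$D[nrow(x$D), ncol(x$D)], nrow(x$path)))
  invisible(x)
}

#' Transfer template QRS boundaries to a test beat along the warping path
#'
#' Walks the optimal path and collects the test indices `m` aligned with
#' the template's annotated QRS-offset and next-beat QRS-onset columns. The
#' outer-bound rule is used: the *last* aligned `m` for the offset (early
#' in the R-to-R segment) and the *first* aligned `m` for the onset (late
#' in the segment), so ambiguity from flat path runs widens rather than
#' narrows the QRS. In the rare collapse where the two coincide, the onset
#' is pushed one sample past the offset and the result flagged.
#'
#' @param table An `mqrs_path_table`.
#' @param template An annotated template (see
#'   [annotate_template_boundaries()]), or a list with `qrs_temp_off` and
#'   `qrs_temp_on` template sample indices.
#' @return List with test-beat indices `qrs_off`, `qrs_on` (1-based) and
#'   logical `collapsed`.
#' @export
locate_qrs <- function(table, template) {
  stopifnot(inherits(table, "mqrs_path_table"))
  off_n <- template$qrs_temp_off
  on_n <- template$qrs_temp_on
  N <- ncol(table$D)
  if (is.null(off_n) || is.null(on_n))
    stop("template QRS boundaries are not annotated")
  if (off_n < 1L || on_n > N || off_n >= on_n)
    stop("template boundary indices outside [1, N] or out of order")
  pm <- table$path[, 1L]
  pn <- table$path[, 2L]
  qrs_off <- max(pm[pn == off_n])
  qrs_on <- min(pm[pn == on_n])
  collapsed <- qrs_on <= qrs_off
  if (collapsed) qrs_on <- min(qrs_off + 1L, nrow(table$D))
  list(qrs_off = qrs_off, qrs_on = qrs_on, collapsed = collapsed)
}

#' Terminal path distance (beat distortion)
#'
#' The accumulated distance at the terminal cell of the DTW table — the
#' raw per-beat distortion score: zero iff an exact warping alignment
#' exists, growing with morphological distortion.
#'
#' @param table An `mqrs_path_table`.
#' @return Nonnegative scalar.
#' @export
distortion <- function(table) {
  stopifnot(inherits(table, "mqrs_path_table"))
  table$D[nrow(table$D), ncol(table$D)]
}

#' Warp one beat against the template
#'
#' Convenience wrapper running [local_distance()], [path_table()],
#' [locate_qrs()] and [distortion()] in one call.
#'
#' @param views A 3 x M view matrix from [build_views()].
#' @param template An annotated `mqrs_template`.
#' @param single_view If `TRUE`, restrict both beat and template to the
#'   amplitude view (classic single-view DTW, used for ablation).
#' @return An object of class `mqrs_warp`: list with `qrs_off`, `qrs_on`,
#'   `distortion`, `collapsed`, and the `path`.
#' @export
mv_dtw <- function(views, template, single_view = FALSE) {
  stopifnot(inherits(template, "mqrs_template"))
  tv <- template$views
  v <- as.matrix(views)
  if (single_view) {
    v <- v[1L, , drop = FALSE]
    tv <- tv[1L, , drop = FALSE]
  }
  d <- cpp_local_distance(v, tv)
  tab <- path_table(d)
  loc <- locate_qrs(tab, template)
  structure(list(qrs_off = loc$qrs_off, qrs_on = loc$qrs_on,
                 distortion = distortion(tab), collapsed = loc$collapsed,
                 path = tab$path),
            class = "mqrs_warp")
}

#' @export
print.mqrs_warp <- function(x, ...) {
  cat(sprintf("<mqrs_warp: qrs_off = %d, qrs_on = %d, distortion = %.6g%s>\n",
              x$qrs_off, x$qrs_on, x$distortion,
              if (x$collapsed) " (collapsed)" else ""))
  invisible(x)
}
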