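#' Construct an ECG record
#'
#' An `ecg_record` is a uniformly sampled single-channel ECG: a numeric
#' vector of samples (arbitrary voltage units), a sampling rate, and a
#' channel role (`"mobile"` or `"chest"`).
#'
#' @param samples Numeric vector of at least two finite sample values.
#' @param fs Sampling rate in Hz (> 0).
#' @param role Channel role, `"mobile"` or `"chest"`.
#' @param start_time Time offset of the first sample in seconds.
#' @param subject_id Opaque subject identifier.
#' @param session `"training"` or `"testing"`.
#' @return An object of class `ecg_record`.
#' @examples
#' rec <- ecg_record(sin(2 * pi * 1.2 * seq(0, 10, by = 1 / 500)), fs = 500)
#' rec
#' @export
ecg_record <- function(samples, fs, role = c("mobile", "chest"),
                       start_time = 0, subject_id = "anon",
                       session = c("training", "testing")) {
  role <- match.arg(role)
  session <- match.arg(session)
  samples <- as.numeric(samples)
  if (length(samples) < 2L) stop("an ecg_record needs at least 2 samples")
  if (!all(is.finite(samples))) stop("ECG samples must all be finite")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("'fs' must be a single positive number (Hz)")
  structure(
    list(samples = samples, fs = fs, role = role, start_time = start_time,
         subject_id = subject_id, session = session),
    class = "ecg_record"
  )
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record: %s lead, %d samples @ %g Hz (%.1f s), subject %s, %s session>\n",
              x$role, length(x$samples), x$fs, length(x$samples) / x$fs,
              x$subject_id, x$session))
  invisible(x)
}

#' @export
length.ecg_record <- function(x) length(x$samples)

#' Construct an annotation track
#'
#' Beat-level annotations for one record: R-peak sample indices, and
#' optionally per-beat QRS onset and offset indices. Indices are 1-based
#' (R convention); file I/O converts to/from the 0-based on-disk format.
#' When onsets/offsets are present they must bracket their R peak:
#' `qrs_on[j] < r_peaks[j] < qrs_off[j]`.
#'
#' @param r_peaks Strictly increasing integer sample indices.
#' @param qrs_on,qrs_off Optional integer vectors, one entry per beat.
#' @param n_samples Optional record length for bounds checking.
#' @return An object of class `ecg_annotations`.
#' @export
ecg_annotations <- function(r_peaks, qrs_on = NULL, qrs_off = NULL,
                            n_samples = NULL) {
  r_peaks <- as.integer(round(r_peaks))
  if (length(r_peaks) == 0L) stop("annotation track needs at least one R peak")
  if (any(diff(r_peaks) <= 0L)) stop("'r_peaks' must be strictly increasing")
  if (any(r_peaks < 1L)) stop("'r_peaks' must be positive sample indices")
  if (!is.null(n_samples) && any(r_peaks > n_samples))
    stop("'r_peaks' outside the record length")
  if (!is.null(qrs_on)) {
    qrs_on <- as.integer(round(qrs_on))
    qrs_off <- as.integer(round(qrs_off))
    if (length(qrs_on) != length(r_peaks) || length(qrs_off) != length(r_peaks))
      stop("'qrs_on'/'qrs_off' must have one entry per R peak")
    if (any(qrs_on >= r_peaks) || any(qrs_off <= r_peaks))
      stop("QRS boundaries must satisfy qrs_on < r_peak < qrs_off per beat")
  }
  structure(list(r_peaks = r_peaks, qrs_on = qrs_on, qrs_off = qrs_off),
            class = "ecg_annotations")
}

#' @export
print.ecg_annotations <- function(x, ...) {
  cat(sprintf("<ecg_annotations: %d R peaks%s>\n", length(x$r_peaks),
              if (is.null(x$qrs_on)) "" else " with QRS boundaries"))
  invisible(x)
}

#' Read an ECG signal from delimited text
#'
#' Accepts one numeric value per line, or a two-column (time, value)
#' delimited file in which case the second column is used. Rows that do not
#' parse to a finite number are rejected.
#'
#' @param path File path.
#' @param fs Sampling rate in Hz.
#' @param role Channel role (`"mobile"` or `"chest"`).
#' @param column Column holding the sample values (default: last column).
#' @param ... Passed on to [ecg_record()].
#' @return An [ecg_record()].
#' @export
read_ecg <- function(path, fs, role = c("mobile", "chest"), column = NULL, ...) {
  if (!file.exists(path)) stop("ECG file not found: ", path)
  tab <- utils::read.table(path, header = FALSE, colClasses = "character",
                           comment.char = "#")
  if (is.null(column)) column <- ncol(tab)
  vals <- suppressWarnings(as.numeric(tab[[column]]))
  if (anyNA(vals) || !all(is.finite(vals)))
    stop("non-numeric or non-finite sample values in ", path)
  ecg_record(vals, fs = fs, role = role, ...)
}

#' Write an ECG signal as plain text (one sample per line)
#'
#' @param rec An [ecg_record()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ecg <- function(rec, path) {
  stopifnot(inherits(rec, "ecg_record"))
  writeLines(formatC(rec$samples, format = "g", digits = 17), path)
  invisible(path)
}

#' Read a QRS annotation file
#'
#' Delimited text with a header naming an `r_peak` column and optionally
#' `qrs_on` / `qrs_off` columns; indices on disk are 0-based sample indices
#' and are converted to 1-based on read.
#'
#' @param path File path.
#' @param n_samples Optional record length for bounds checking.
#' @return An [ecg_annotations()].
#' @export
read_annotations <- function(path, n_samples = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  tab <- utils::read.table(path, header = TRUE)
  if (!"r_peak" %in% names(tab)) stop("annotation file must have an 'r_peak' column")
  ecg_annotations(
    r_peaks = tab$r_peak + 1L,
    qrs_on = if ("qrs_on" %in% names(tab)) tab$qrs_on + 1L,
    qrs_off = if ("qrs_off" %in% names(tab)) tab$qrs_off + 1L,
    n_samples = n_samples
  )
}

#' Write a QRS annotation file (0-based indices, tab-separated)
#'
#' @param ann An [ecg_annotations()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  stopifnot(inherits(ann, "ecg_annotations"))
  tab <- data.frame(r_peak = ann$r_peaks - 1L)
  if (!is.null(ann$qrs_on)) {
    tab$qrs_on <- ann$qrs_on - 1L
    tab$qrs_off <- ann$qrs_off - 1L
  }
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
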