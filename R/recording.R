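#' Multichannel EEG recordings
#'
#' `eeg_recording()` bundles a channels-by-samples potential matrix (in
#' microvolts) with its sampling rate, montage, reference state and
#' condition/run annotations. It is the container consumed by the
#' preprocessing chain, the spectral analysis and the microstate fitting.
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param fs sampling rate in Hz.
#' @param montage a [montage] whose channels match the rows of `data`.
#' @param reference "original" or "average".
#' @param annotations tibble with columns `onset` (s), `duration` (s),
#'   `condition`, `run`; may be empty.
#' @return An `eeg_recording` object.
#' @export
eeg_recording <- function(data, fs, montage,
                          reference = c("original", "average"),
                          annotations = NULL) {
  reference <- match.arg(reference)
  data <- as.matrix(data)
  if (!all(is.finite(data))) stop_microdyn("EEG data must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop_microdyn("fs must be a positive scalar")
  }
  if (nrow(data) != nrow(montage)) {
    stop_microdyn("data has %d rows but montage has %d channels",
                  nrow(data), nrow(montage))
  }
  rownames(data) <- montage$channel
  if (is.null(annotations)) {
    annotations <- tibble::tibble(onset = numeric(), duration = numeric(),
                                  condition = character(), run = integer())
  }
  annotations <- tibble::as_tibble(annotations)
  dur <- ncol(data) / fs
  if (nrow(annotations) > 0 &&
      any(annotations$onset < 0 | annotations$onset + annotations$duration >
            dur + 1e-9)) {
    stop_microdyn("annotations extend beyond the record duration (%.2f s)", dur)
  }
  structure(
    list(data = data, fs = fs, montage = montage, reference = reference,
         annotations = annotations),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %s reference\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              x$reference))
  if (nrow(x$annotations) > 0) {
    cat(sprintf("  %d annotations: %s\n", nrow(x$annotations),
                paste(unique(x$annotations$condition), collapse = ", ")))
  }
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

#' Tidy view of an EEG recording
#'
#' @param x an `eeg_recording`.
#' @param ... unused.
#' @return tibble with columns `time`, `channel`, `value`.
#' @export
as_tibble.eeg_recording <- function(x, ...) {
  tibble::tibble(
    time = rep((seq_len(ncol(x$data)) - 1L) / x$fs, each = nrow(x$data)),
    channel = rep(rownames(x$data), times = ncol(x$data)),
    value = as.vector(x$data)
  )
}

n_samples <- function(rec) ncol(rec$data)

#' Categorical microstate label sequences
#'
#' A `label_sequence` stores one microstate class label per sample, with
#' the sampling rate and class count needed by the sequence statistics.
#' Labels are integers in `1..n_classes`.
#'
#' @param labels integer vector of class labels.
#' @param fs sampling rate of the sequence in Hz.
#' @param n_classes number of classes (defaults to `max(labels)`).
#' @param condition optional condition tag.
#' @return A `label_sequence` object (integer vector with attributes).
#' @export
label_sequence <- function(labels, fs, n_classes = max(labels),
                           condition = NA_character_) {
  labels <- as.integer(labels)
  if (length(labels) == 0L) stop_microdyn("label sequence must be non-empty")
  if (any(labels < 1L | labels > n_classes)) {
    stop_microdyn("labels must lie in 1..n_classes")
  }
  structure(labels, fs = fs, n_classes = as.integer(n_classes),
            condition = condition, class = "label_sequence")
}

#' @export
print.label_sequence <- function(x, ...) {
  cat(sprintf("<label_sequence> %d samples @ %g Hz, %d classes\n",
              length(x), attr(x, "fs"), attr(x, "n_classes")))
  invisible(x)
}

#' @export
`[.label_sequence` <- function(x, i) {
  label_sequence(unclass(x)[i], fs = attr(x, "fs"),
                 n_classes = attr(x, "n_classes"),
                 condition = attr(x, "condition"))
}

seq_fs <- function(seq) attr(seq, "fs")
seq_classes <- function(seq) attr(seq, "n_classes")
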