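#' Single-channel EEG segment
#'
#' Container for one single-channel EEG recording window: a numeric sample
#' vector (microvolts), its sampling rate, an optional class label and an
#' opaque source identifier.
#'
#' @param samples Numeric vector of amplitudes; length >= 2, all finite.
#' @param fs Sampling rate in Hz (> 0).
#' @param label Optional class tag (0/1 integer or a named state); `NULL`
#'   when unlabeled.
#' @param source_id Opaque identifier string (e.g. the file stem).
#' @return An object of class `eeg_segment`.
#' @export
eeg_segment <- function(samples, fs, label = NULL, source_id = "") {
  samples <- as.numeric(samples)
  if (length(samples) < 2L) {
    stop("an EEG segment needs at least 2 samples", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("EEG segment contains non-finite samples", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("fs must be a single positive number (Hz)", call. = FALSE)
  }
  structure(list(samples = samples, fs = fs, label = label,
                 source_id = as.character(source_id)),
            class = "eeg_segment")
}

#' @rdname eeg_segment
#' @param x Object to coerce/test.
#' @export
as_eeg_segment <- function(x) {
  if (inherits(x, "eeg_segment")) return(x)
  if (is.numeric(x)) {
    stop("a bare numeric vector has no sampling rate; use eeg_segment(x, fs)",
         call. = FALSE)
  }
  stop("cannot coerce ", class(x)[1L], " to eeg_segment", call. = FALSE)
}

segment_samples <- function(seg) {
  if (inherits(seg, "eeg_segment")) seg$samples else as.numeric(seg)
}

segment_fs <- function(seg, default = NA_real_) {
  if (inherits(seg, "eeg_segment")) seg$fs else default
}

#' @export
print.eeg_segment <- function(x, ...) {
  lab <- if (is.null(x$label)) "unlabeled" else paste0("label = ", x$label)
  cat("<eeg_segment> ", length(x$samples), " samples @ ", x$fs, " Hz, ",
      lab, if (nzchar(x$source_id)) paste0(" [", x$source_id, "]"), "\n",
      sep = "")
  invisible(x)
}
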