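#' Zero-phase Butterworth band-pass filter
#'
#' Designs an `order`-th order Butterworth filter and applies it
#' forward-backward (zero phase, so feature timing is not distorted).
#' When the upper edge reaches the Nyquist frequency (`high >=
#' 0.99 * fs/2`, e.g. the 0.01--86.8 Hz band at fs = 173.61 Hz) a band-pass
#' design is degenerate, so the filter degrades gracefully to a high-pass at
#' `low` -- full band minus drift -- with a warning. A `low` of zero
#' likewise yields a low-pass at `high`.
#'
#' @param seg An [eeg_segment()].
#' @param low,high Band edges in Hz, `0 <= low < high`; `high = NULL` means
#'   the Nyquist frequency.
#' @param order Filter order (default 4).
#' @return The filtered [eeg_segment()], same length as the input.
#' @export
bandpass <- function(seg, low = 0.01, high = NULL, order = 4) {
  seg <- as_eeg_segment(seg)
  fs <- seg$fs
  nyq <- fs / 2
  if (is.null(high)) high <- nyq
  if (!is.numeric(low) || !is.numeric(high) || low < 0 || low >= high) {
    stop("need 0 <= low < high (got low = ", low, ", high = ", high, ")",
         call. = FALSE)
  }
  if (order < 1) stop("order must be >= 1", call. = FALSE)
  if (low >= nyq) {
    stop("low edge ", low, " Hz is at or above Nyquist (", nyq,
         " Hz); fs too low for the requested band", call. = FALSE)
  }
  if (high >= 0.99 * nyq) {
    if (low <= 0) return(seg) # nothing to remove
    warning("upper edge ", high, " Hz is at the Nyquist frequency; ",
            "applying a high-pass at ", low, " Hz instead of a band-pass",
            call. = FALSE)
    flt <- signal::butter(order, low / nyq, type = "high")
  } else if (low <= 0) {
    flt <- signal::butter(order, high / nyq, type = "low")
  } else {
    flt <- signal::butter(order, c(low, high) / nyq, type = "pass")
  }
  out <- seg
  out$samples <- as.numeric(signal::filtfilt(flt, seg$samples))
  out
}
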