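#' Single-channel ECG sample stream
#'
#' A `signal_record` is the package's container for a uniformly sampled
#' single-channel waveform: sample values in millivolts, the sampling rate in
#' Hz, an optional class label and a free-text provenance identifier.
#'
#' @param samples Numeric vector of sample values (mV). Must be non-empty and
#'   finite.
#' @param fs Sampling rate in Hz (single positive number).
#' @param label Optional class label (e.g. `"N"`, `"RBBB"`, `"WPW"`).
#' @param source_id Free-text provenance string.
#'
#' @return An object of class `signal_record`: a list with elements
#'   `samples`, `fs`, `label`, `source_id`.
#' @examples
#' rec <- signal_record(sin(2 * pi * 5 * (0:359) / 360), fs = 360)
#' rec
#' @export
signal_record <- function(samples, fs, label = NULL, source_id = "") {
  samples <- as.numeric(samples)
  stopifnot_scalar_pos(fs, "fs")
  if (length(samples) == 0L) {
    stop("`samples` must be non-empty", call. = FALSE)
  }
  if (any(!is.finite(samples))) {
    stop("`samples` must be finite (no NA/NaN/Inf)", call. = FALSE)
  }
  if (!is.null(label)) label <- as.character(label)[1L]
  structure(
    list(samples = samples, fs = as.numeric(fs), label = label,
         source_id = as.character(source_id)[1L]),
    class = "signal_record"
  )
}

#' @export
print.signal_record <- function(x, ...) {
  cat(sprintf("<signal_record> %d samples @ %g Hz (%.3f s)%s%s\n",
              length(x$samples), x$fs, length(x$samples) / x$fs,
              if (is.null(x$label)) "" else paste0(", label ", x$label),
              if (nzchar(x$source_id)) paste0(" [", x$source_id, "]") else ""))
  invisible(x)
}

#' One fixed-length beat window
#'
#' A `ecg_segment` holds one rectangular window cut from a (filtered,
#' decimated) record: the samples, the effective sampling rate after
#' decimation, the propagated class label and the window's centre time within
#' the parent record.
#'
#' @param samples Numeric vector of window samples (mV).
#' @param fs_effective Sampling rate of the window in Hz.
#' @param label Class label carried from the parent record (may be `NULL`).
#' @param t_center Centre time of the window in seconds.
#'
#' @return An object of class `ecg_segment`.
#' @export
ecg_segment <- function(samples, fs_effective, label = NULL, t_center = NA_real_) {
  samples <- as.numeric(samples)
  stopifnot_scalar_pos(fs_effective, "fs_effective")
  if (length(samples) == 0L) stop("`samples` must be non-empty", call. = FALSE)
  if (any(!is.finite(samples))) stop("`samples` must be finite", call. = FALSE)
  if (!is.null(label)) label <- as.character(label)[1L]
  structure(
    list(samples = samples, fs_effective = as.numeric(fs_effective),
         label = label, t_center = as.numeric(t_center)),
    class = "ecg_segment"
  )
}

#' @export
print.ecg_segment <- function(x, ...) {
  cat(sprintf("<ecg_segment> %d samples @ %g Hz, centre %.3f s%s\n",
              length(x$samples), x$fs_effective, x$t_center,
              if (is.null(x$label)) "" else paste0(", label ", x$label)))
  invisible(x)
}
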