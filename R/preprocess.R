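# Front-end preprocessing: band-pass FIR denoising, aliasing-safe
# decimation, and blind fixed-window segmentation.

#' Band-pass FIR filter specification
#'
#' The denoising filter is a linear-phase band-pass FIR designed offline for
#' the clinically useful ECG band. The upper cut-off must stay below half
#' the sampling rate.
#'
#' @param fc_low Lower cut-off in Hz (default 0.5).
#' @param fc_high Upper cut-off in Hz (default 50).
#' @param order Filter order; must be even so the group delay `order/2` is
#'   an integer number of samples (default 122, i.e. 123 taps).
#' @param fs Design sampling rate in Hz (default 360).
#'
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(fc_low = 0.5, fc_high = 50, order = 122, fs = 360) {
  stopifnot_scalar_pos(fs, "fs")
  stopifnot_scalar_pos(fc_low, "fc_low")
  stopifnot_scalar_pos(fc_high, "fc_high")
  if (fc_low >= fc_high) stop("need fc_low < fc_high", call. = FALSE)
  if (fc_high >= fs / 2) {
    stop(sprintf(
      "fc_high (%g Hz) must be kept below half the sampling rate (fs/2 = %g Hz)",
      fc_high, fs / 2), call. = FALSE)
  }
  if (order < 2 || order %% 2 != 0) {
    stop("`order` must be a positive even integer", call. = FALSE)
  }
  structure(list(fc_low = fc_low, fc_high = fc_high,
                 order = as.integer(order), fs = fs),
            class = "filter_spec")
}

#' Design the band-pass denoising filter
#'
#' Windowed-sinc (Hamming) design at the requested fixed order. The returned
#' coefficient vector is explicitly symmetrised, so linear phase holds
#' exactly, not just to rounding.
#'
#' @param spec A [filter_spec()].
#' @return Numeric vector of `order + 1` coefficients, with the spec
#'   attached as attribute `"filter_spec"`.
#' @examples
#' b <- design_bandpass(filter_spec())
#' length(b)                  # 123
#' all(b == rev(b))           # exact linear phase
#' @export
design_bandpass <- function(spec = filter_spec()) {
  if (!inherits(spec, "filter_spec")) {
    stop("`spec` must be a filter_spec", call. = FALSE)
  }
  b <- signal::fir1(spec$order, c(spec$fc_low, spec$fc_high) / (spec$fs / 2),
                    type = "pass")
  b <- as.numeric(b)
  b <- (b + rev(b)) / 2  # enforce exact coefficient symmetry
  attr(b, "filter_spec") <- spec
  b
}

#' Frequency response magnitude of an FIR filter
#'
#' Evaluates `|H(f)| = |sum_k b_k exp(-2 pi i f k / fs)|` at the requested
#' frequencies.
#'
#' @param coeffs FIR coefficient vector.
#' @param f Frequencies in Hz.
#' @param fs Sampling rate in Hz.
#' @return Numeric vector of magnitudes.
#' @export
filter_response <- function(coeffs, f, fs) {
  k <- seq_along(coeffs) - 1
  vapply(f, function(fi) {
    Mod(sum(coeffs * exp(-2i * pi * fi * k / fs)))
  }, numeric(1))
}

#' Apply the denoising filter
#'
#' Linear convolution with the FIR coefficients, followed by an integer
#' shift of `order/2` samples to cancel the linear-phase group delay, so the
#' output is the same length as the input and beat peaks stay aligned. Edge
#' samples are implicitly zero-padded.
#'
#' @param x A [signal_record()]; must be longer than the filter.
#' @param coeffs Coefficients from [design_bandpass()].
#' @return A filtered [signal_record()] with the same length and `fs`.
#' @export
apply_filter <- function(x, coeffs) {
  if (!inherits(x, "signal_record")) {
    stop("`x` must be a signal_record", call. = FALSE)
  }
  n <- length(x$samples)
  l <- length(coeffs)
  if (n <= l) {
    stop(sprintf("record (%d samples) must be longer than the filter (%d taps)",
                 n, l), call. = FALSE)
  }
  delay <- (l - 1) %/% 2
  full <- stats::convolve(x$samples, rev(as.numeric(coeffs)), type = "open")
  y <- full[(delay + 1):(delay + n)]
  signal_record(y, fs = x$fs, label = x$label,
                source_id = paste0(x$source_id, "|bp"))
}

#' Largest alias-safe decimation factor
#'
#' For a signal band-limited to `fmax`, decimation by `D` is alias-free when
#' `D <= fs / (2 * fmax)`; the function returns that (real-valued) bound.
#' With `fs = 360` and `fmax = 50` the bound is 3.6, so `D = 3` is the
#' largest safe integer factor.
#'
#' @param fs Sampling rate in Hz.
#' @param fmax Signal bandwidth in Hz (the band-pass upper cut-off).
#' @return `fs / (2 * fmax)`.
#' @examples
#' max_decimation_factor(360, 50)  # 3.6
#' @export
max_decimation_factor <- function(fs, fmax) {
  stopifnot_scalar_pos(fs, "fs")
  stopifnot_scalar_pos(fmax, "fmax")
  fs / (2 * fmax)
}

#' Decimate a record
#'
#' Keeps samples at indices 1, 1+D, 1+2D, ... (phase 0) and divides the
#' sampling rate by `D`. Unless `force = TRUE`, `D` is checked against the
#' alias-safety bound of [max_decimation_factor()].
#'
#' @param x A [signal_record()].
#' @param d Integer decimation factor >= 1.
#' @param force Skip the alias-safety check (default `FALSE`).
#' @param fmax Band limit used for the check, in Hz (default 50, the
#'   denoising filter's upper cut-off).
#' @return The decimated [signal_record()] with `fs = x$fs / d`.
#' @export
decimate_signal <- function(x, d, force = FALSE, fmax = 50) {
  if (!inherits(x, "signal_record")) {
    stop("`x` must be a signal_record", call. = FALSE)
  }
  if (!is.numeric(d) || length(d) != 1L || d < 1 || d != round(d)) {
    stop("`d` must be a single integer >= 1", call. = FALSE)
  }
  d <- as.integer(d)
  bound <- max_decimation_factor(x$fs, fmax)
  if (!force && d > bound) {
    stop(sprintf(
      "aliasing risk: D = %d exceeds the bound Fs/(2*fmax) = %g/(2*%g) = %g; use force = TRUE to override",
      d, x$fs, fmax, bound), call. = FALSE)
  }
  idx <- seq(1L, length(x$samples), by = d)
  signal_record(x$samples[idx], fs = x$fs / d, label = x$label,
                source_id = paste0(x$source_id, sprintf("|D%d", d)))
}

#' Segment a record into fixed-length beat windows
#'
#' Blind tiling with consecutive non-overlapping rectangular windows of
#' `round(seg_len_s * fs)` samples; the trailing partial window is
#' discarded. No R-peak detection is attempted: the window centre time is
#' recorded as the segment's `t_center` and the record label is propagated.
#'
#' @param x A [signal_record()].
#' @param seg_len_s Window length in seconds (default 0.9).
#' @return A list of [ecg_segment()]s; empty (with a warning) if the record
#'   is shorter than one window.
#' @export
segment_signal <- function(x, seg_len_s = 0.9) {
  if (!inherits(x, "signal_record")) {
    stop("`x` must be a signal_record", call. = FALSE)
  }
  stopifnot_scalar_pos(seg_len_s, "seg_len_s")
  w <- round(seg_len_s * x$fs)
  if (w < 1) stop("window shorter than one sample", call. = FALSE)
  nseg <- length(x$samples) %/% w
  if (nseg == 0L) {
    warning(sprintf("record of %d samples is shorter than one %d-sample window; no segments",
                    length(x$samples), w))
    return(list())
  }
  lapply(seq_len(nseg), function(j) {
    idx <- ((j - 1L) * w + 1L):(j * w)
    ecg_segment(x$samples[idx], fs_effective = x$fs, label = x$label,
                t_center = ((j - 1) * w + (w - 1) / 2) / x$fs)
  })
}
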