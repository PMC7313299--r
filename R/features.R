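# Per-subband statistics and feature-matrix assembly. Four statistics per
# subband, four subbands, 16 features per beat.

#' Subband energy
#'
#' The sum of absolute coefficient values, `sum(|c|)` (an L1 sum). That is
#' the definition used throughout the pipeline; the conventional quadratic
#' energy `sum(c^2)` is available as `mode = "l2"`.
#'
#' @param c Numeric coefficient sequence (non-empty).
#' @param mode `"l1"` (default) or `"l2"`.
#' @return A single non-negative number.
#' @examples
#' subband_energy(c(1, -2, 3))  # 6
#' @export
subband_energy <- function(c, mode = c("l1", "l2")) {
  mode <- match.arg(mode)
  if (length(c) == 0L) stop("empty coefficient sequence", call. = FALSE)
  if (mode == "l1") sum(abs(c)) else sum(c^2)
}

#' Subband kurtosis
#'
#' Pearson (non-excess) kurtosis `m4 / m2^2` with population moments about
#' the mean; 3 for a Gaussian, lower bound 1. A zero-variance (degenerate)
#' subband returns 0 with a warning.
#'
#' @param c Numeric coefficient sequence of length >= 4.
#' @return A single number (>= 1 when defined, 0 for degenerate input).
#' @export
subband_kurtosis <- function(c) {
  if (length(c) < 4L) stop("need at least 4 coefficients", call. = FALSE)
  m <- mean(c)
  m2 <- mean((c - m)^2)
  if (m2 == 0) {
    warning("zero-variance subband; kurtosis undefined, returning 0")
    return(0)
  }
  mean((c - m)^4) / m2^2
}

#' Peak positive / peak negative value
#'
#' `peak_positive` is the largest positive coefficient (0 if none exists);
#' `peak_negative` is the most negative coefficient (0 if none exists), so
#' `PV >= 0 >= NV` always.
#'
#' @param c Numeric coefficient sequence (non-empty).
#' @return A single number.
#' @examples
#' peak_positive(c(-1, 2, 0.5))  # 2
#' peak_negative(c(-1, 2, 0.5))  # -1
#' @export
peak_positive <- function(c) {
  if (length(c) == 0L) stop("empty coefficient sequence", call. = FALSE)
  m <- max(c)
  if (m > 0) m else 0
}

#' @rdname peak_positive
#' @export
peak_negative <- function(c) {
  if (length(c) == 0L) stop("empty coefficient sequence", call. = FALSE)
  m <- min(c)
  if (m < 0) m else 0
}

#' Extract the 16-feature vector of one decomposition
#'
#' Energy, kurtosis, peak positive and peak negative value of each of
#' `d1, d2, d3, a3`, in the fixed subband-major order of [feature_names()].
#'
#' @param dec A [decompose3()] result.
#' @param energy Energy flavour passed to [subband_energy()].
#' @return Named numeric vector of length 16.
#' @export
extract_features <- function(dec, energy = c("l1", "l2")) {
  energy <- match.arg(energy)
  if (!inherits(dec, "wavelet_decomposition")) {
    stop("`dec` must be a wavelet_decomposition", call. = FALSE)
  }
  out <- unlist(lapply(c("d1", "d2", "d3", "a3"), function(sb) {
    c <- dec[[sb]]
    c(subband_energy(c, energy), subband_kurtosis(c),
      peak_positive(c), peak_negative(c))
  }))
  names(out) <- feature_names()
  out
}

#' Assemble the feature matrix
#'
#' One row per segment, in input order (no hidden sorting), with the
#' segment labels carried through as the final `label` column. With 150
#' beats per class for the three classes this is the 450 x 16 matrix the
#' classifier consumes.
#'
#' @param segments List of labelled [ecg_segment()]s.
#' @param wavelet_order Daubechies order for [decompose3()] (default 4).
#' @param energy Energy flavour (default `"l1"`).
#' @return A data frame of class `feature_matrix`: 16 numeric feature
#'   columns plus `label`.
#' @export
build_feature_matrix <- function(segments, wavelet_order = 4,
                                 energy = c("l1", "l2")) {
  energy <- match.arg(energy)
  if (length(segments) == 0L) stop("need at least one segment", call. = FALSE)
  labels <- vapply(segments, function(s) {
    if (is.null(s$label) || is.na(s$label)) NA_character_ else s$label
  }, character(1))
  if (anyNA(labels)) {
    stop(sprintf("unlabeled segment at position %d", which(is.na(labels))[1L]),
         call. = FALSE)
  }
  rows <- vapply(segments, function(s) {
    extract_features(decompose3(s, order = wavelet_order), energy = energy)
  }, numeric(16))
  fm <- as.data.frame(t(rows))
  names(fm) <- feature_names()
  fm$label <- labels
  rownames(fm) <- NULL
  class(fm) <- c("feature_matrix", "data.frame")
  fm
}
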