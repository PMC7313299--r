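# Three-level Daubechies filter-bank decomposition.
#
# Each analysis level convolves with the half-band low-pass g and high-pass
# h and keeps every second output (the 2n - k stencil), with periodic
# boundary extension so each level exactly halves the length and the
# transform stays orthonormal. Inputs are zero-padded to a multiple of 2^3
# before the cascade, giving the fixed length contract 108 -> 112 ->
# (d1 = 56, d2 = 28, d3 = 14, a3 = 14).

# Daubechies scaling coefficients by spectral factorization: roots of the
# half-band polynomial P(y) mapped to z, minimum-phase half selected, then
# multiplied by ((1 + z)/2)^p. A few Newton polish passes push root accuracy
# to ~1e-13 even at order 10.
.daub_scaling <- function(p) {
  if (p == 1) return(rep(1 / sqrt(2), 2))
  convp <- function(a, b) {
    out <- complex(length(a) + length(b) - 1L)
    for (i in seq_along(a)) {
      j <- i:(i + length(b) - 1L)
      out[j] <- out[j] + a[i] * b
    }
    out
  }
  zy <- c(-1, 2, -1) / 4  # z * y(z) with y = (2 - z - 1/z)/4
  poly <- complex(2L * (p - 1L) + 1L)
  for (k in 0:(p - 1)) {
    term <- as.complex(choose(p - 1 + k, k))
    if (k > 0) for (j in 1:k) term <- convp(term, zy)
    term <- c(complex(p - 1 - k), term)
    poly[seq_along(term)] <- poly[seq_along(term)] + term
  }
  r <- polyroot(poly)
  dpoly <- poly[-1] * seq_len(length(poly) - 1L)
  for (it in 1:8) {
    f <- vapply(r, function(z) sum(poly * z^(seq_along(poly) - 1)), complex(1))
    fp <- vapply(r, function(z) sum(dpoly * z^(seq_along(dpoly) - 1)), complex(1))
    r <- r - f / fp
  }
  rin <- r[Mod(r) < 1]
  if (length(rin) != p - 1L) {
    stop("spectral factorization failed", call. = FALSE)  # not reachable for p <= 10
  }
  R <- as.complex(1)
  for (ri in rin) R <- convp(R, c(-ri, 1))
  R <- R / sum(R)  # normalise R(1) = 1
  g <- sqrt(2) * Re(R)
  for (j in 1:p) g <- Re(convp(as.complex(g), as.complex(c(0.5, 0.5))))
  rev(g)  # natural (causal, energy-early) coefficient order
}

.daub_cache <- new.env(parent = emptyenv())

#' Daubechies half-band filter pair
#'
#' Computes the orthonormal Daubechies scaling (low-pass) coefficients `g`
#' of the requested order and derives the quadrature-mirror high-pass
#' `h_k = (-1)^k g_{Kg-1-k}` (0-based indexing). `sum(g) = sqrt(2)` and
#' `sum(h) = 0` hold to ~1e-12.
#'
#' @param order Wavelet order, 1 (Haar) through 10.
#' @return An object of class `wavelet_filters`: list with `g`, `h` and the
#'   tap count `Kg = 2 * order`.
#' @examples
#' daubechies_filters(1)$g  # (1/sqrt(2), 1/sqrt(2))
#' @export
daubechies_filters <- function(order) {
  if (!is.numeric(order) || length(order) != 1L || order != round(order) ||
      order < 1 || order > 10) {
    stop("`order` must be an integer in 1..10 (db1..db10)", call. = FALSE)
  }
  key <- as.character(order)
  if (is.null(.daub_cache[[key]])) {
    g <- .daub_scaling(as.integer(order))
    kg <- length(g)
    h <- (-1)^(seq_len(kg) - 1) * rev(g)
    .daub_cache[[key]] <- structure(
      list(g = g, h = h, Kg = kg, order = as.integer(order)),
      class = "wavelet_filters")
  }
  .daub_cache[[key]]
}

#' @export
print.wavelet_filters <- function(x, ...) {
  cat(sprintf("<wavelet_filters> db%d, %d taps\n", x$order, x$Kg))
  invisible(x)
}

# Periodized convolve-and-downsample:
# out[n] = sum_k f[k] x[(2n - k + shift) mod N], n = 1..N/2. The circular
# shift Kg/2 - 1 cancels the half-band filter's group delay inside the
# periodic window, so subband coefficients stay aligned with the beat.
.pconv_down <- function(x, f, shift) {
  n <- length(x)
  half <- n %/% 2L
  n2 <- 2L * seq_len(half) + shift
  out <- numeric(half)
  for (k in seq_along(f)) out <- out + f[k] * x[((n2 - k) %% n) + 1L]
  out
}

#' One analysis level of the filter bank
#'
#' Splits an even-length sequence into approximation and detail halves:
#' convolution with the half-band low-pass/high-pass followed by
#' downsampling by two, with periodic boundary extension. Output lengths are
#' exactly `length(x) / 2`.
#'
#' @param x Numeric sequence of even length.
#' @param filters A [daubechies_filters()] pair.
#' @return List with components `a` (approximation) and `d` (detail).
#' @export
dwt_level <- function(x, filters) {
  if (!inherits(filters, "wavelet_filters")) {
    stop("`filters` must come from daubechies_filters()", call. = FALSE)
  }
  if (length(x) %% 2L != 0L || length(x) == 0L) {
    stop("`x` must have even, positive length (pad upstream)", call. = FALSE)
  }
  shift <- filters$Kg %/% 2L - 1L
  list(a = .pconv_down(x, rev(filters$g), shift),
       d = .pconv_down(x, rev(filters$h), shift))
}

#' One synthesis level (inverse of [dwt_level()])
#'
#' @param a Approximation coefficients.
#' @param d Detail coefficients (same length as `a`).
#' @param filters The same [daubechies_filters()] used for analysis.
#' @return Numeric sequence of length `2 * length(a)`.
#' @export
idwt_level <- function(a, d, filters) {
  if (length(a) != length(d)) {
    stop("`a` and `d` must have equal length", call. = FALSE)
  }
  n <- 2L * length(a)
  n2 <- 2L * seq_len(length(a)) + (filters$Kg %/% 2L - 1L)
  gr <- rev(filters$g)
  hr <- rev(filters$h)
  x <- numeric(n)
  for (k in seq_along(gr)) {
    idx <- ((n2 - k) %% n) + 1L
    x[idx] <- x[idx] + gr[k] * a + hr[k] * d
  }
  x
}

#' Three-level wavelet decomposition of a beat segment
#'
#' Zero-pads the segment to the next multiple of 8, then cascades three
#' [dwt_level()] calls on successive approximations, yielding the detail
#' subbands `d1`, `d2`, `d3` and the coarse approximation `a3`. Nominal band
#' edges are the dyadic halving of `[0, fs_effective/2]`.
#'
#' @param seg An [ecg_segment()], or a bare numeric vector (then
#'   `fs_effective` must be given).
#' @param order Daubechies order (default 4).
#' @param fs_effective Sampling rate in Hz; taken from the segment when
#'   omitted.
#' @return An object of class `wavelet_decomposition` with the four
#'   coefficient sequences, `level_of`, `band_edges`, `fs_effective`, the
#'   original and padded lengths, and the propagated `label`.
#' @examples
#' seg <- ecg_segment(sin(2 * pi * 7 * (0:107) / 120), 120)
#' dec <- decompose3(seg)
#' lengths(dec[c("d1", "d2", "d3", "a3")])  # 56 28 14 14
#' @export
decompose3 <- function(seg, order = 4, fs_effective = NULL) {
  if (inherits(seg, "ecg_segment")) {
    x <- seg$samples
    fs_effective <- seg$fs_effective
    label <- seg$label
  } else if (is.numeric(seg)) {
    if (is.null(fs_effective)) {
      stop("`fs_effective` is required for bare numeric input", call. = FALSE)
    }
    x <- as.numeric(seg)
    label <- NULL
  } else {
    stop("`seg` must be an ecg_segment or numeric vector", call. = FALSE)
  }
  if (length(x) == 0L) stop("empty segment", call. = FALSE)
  filters <- daubechies_filters(order)
  n_orig <- length(x)
  n_pad <- 8L * as.integer(ceiling(n_orig / 8))
  x <- c(x, numeric(n_pad - n_orig))
  l1 <- dwt_level(x, filters)
  l2 <- dwt_level(l1$a, filters)
  l3 <- dwt_level(l2$a, filters)
  nyq <- fs_effective / 2
  structure(
    list(d1 = l1$d, d2 = l2$d, d3 = l3$d, a3 = l3$a,
         level_of = c(d1 = 1L, d2 = 2L, d3 = 3L, a3 = 3L),
         band_edges = list(a3 = c(0, nyq / 8), d3 = c(nyq / 8, nyq / 4),
                           d2 = c(nyq / 4, nyq / 2), d1 = c(nyq / 2, nyq)),
         fs_effective = fs_effective, n_orig = n_orig, n_padded = n_pad,
         order = as.integer(order), label = label),
    class = "wavelet_decomposition"
  )
}

#' @export
print.wavelet_decomposition <- function(x, ...) {
  cat(sprintf("<wavelet_decomposition> db%d, %d -> %d samples; d1/d2/d3/a3 = %d/%d/%d/%d\n",
              x$order, x$n_orig, x$n_padded,
              length(x$d1), length(x$d2), length(x$d3), length(x$a3)))
  invisible(x)
}

#' Inverse three-level decomposition
#'
#' Runs the synthesis cascade and truncates to `out_len` (the original
#' segment length by default). With the same order as the analysis this is
#' a perfect reconstruction up to rounding (orthonormal filter bank).
#'
#' @param dec A `wavelet_decomposition` from [decompose3()].
#' @param order Daubechies order; defaults to the one recorded in `dec`.
#' @param out_len Output length (default `dec$n_orig`).
#' @return Numeric vector of length `out_len`.
#' @export
reconstruct3 <- function(dec, order = dec$order, out_len = dec$n_orig) {
  if (!inherits(dec, "wavelet_decomposition")) {
    stop("`dec` must be a wavelet_decomposition", call. = FALSE)
  }
  if (length(dec$a3) != length(dec$d3) ||
      length(dec$d2) != 2L * length(dec$d3) ||
      length(dec$d1) != 2L * length(dec$d2)) {
    stop("subband lengths are inconsistent with a 3-level cascade",
         call. = FALSE)
  }
  filters <- daubechies_filters(order)
  a2 <- idwt_level(dec$a3, dec$d3, filters)
  a1 <- idwt_level(a2, dec$d2, filters)
  x <- idwt_level(a1, dec$d1, filters)
  if (out_len > length(x)) {
    stop("`out_len` exceeds the padded length", call. = FALSE)
  }
  x[seq_len(out_len)]
}
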