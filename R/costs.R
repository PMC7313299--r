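# Compression and computational-cost accounting: how much less data the
# feature front end transmits, and how many additions/multiplications the
# multirate wavelet decomposition saves over a fixed-rate one.

#' Compression ratio
#'
#' `R_COMP = Nr / P`: conventional samples per analysis window over features
#' transmitted per instance. With a one-second 360 Hz window and the
#' 16-feature vector this is 22.5.
#'
#' @param nr Samples per conventional window.
#' @param p Features per instance.
#' @return The ratio `nr / p`.
#' @examples
#' compression_ratio(360, 16)  # 22.5
#' @export
compression_ratio <- function(nr, p) {
  stopifnot_scalar_pos(nr, "nr")
  stopifnot_scalar_pos(p, "p")
  nr / p
}

#' Fixed-rate wavelet-decomposition cost
#'
#' Operation count of the 3-level half-band cascade run at the full rate:
#' `3.5 * Kg * Nr` additions and the same number of multiplications. The
#' 3.5 is the cascade sum `2 * (1 + 1/2 + 1/4)` - two filters per level,
#' each level consuming half the previous rate.
#'
#' @param kg Half-band filter taps.
#' @param nr Samples per window at the full rate.
#' @return Named numeric vector `c(additions, multiplications)`.
#' @export
complexity_fixed <- function(kg, nr) {
  stopifnot_scalar_pos(kg, "kg")
  stopifnot_scalar_pos(nr, "nr")
  v <- 3.5 * kg * nr
  c(additions = v, multiplications = v)
}

#' Multirate wavelet-decomposition cost
#'
#' The same cascade fed with the decimated stream: each window now holds
#' `Nr / D` samples, so the cost is `(3.5 / D) * Kg * Nr` additions and
#' multiplications. The default `D = 4` reproduces the printed coefficient
#' `0.875 * Kg * Nr`.
#'
#' @inheritParams complexity_fixed
#' @param d Decimation factor (default 4).
#' @return Named numeric vector `c(additions, multiplications)`.
#' @export
complexity_proposed <- function(kg, nr, d = 4) {
  stopifnot_scalar_pos(kg, "kg")
  stopifnot_scalar_pos(nr, "nr")
  stopifnot_scalar_pos(d, "d")
  v <- (3.5 / d) * kg * nr
  c(additions = v, multiplications = v)
}

#' Computational gain of the multirate front end
#'
#' Ratio of fixed-rate to multirate operation counts; algebraically equal to
#' `D` for every `(Kg, Nr)`, hence the 4-fold reduction at `D = 4`.
#'
#' @inheritParams complexity_proposed
#' @return The gain (a ratio).
#' @examples
#' computational_gain(8, 324, d = 4)  # 4
#' @export
computational_gain <- function(kg, nr, d = 4) {
  unname(complexity_fixed(kg, nr)["additions"] /
           complexity_proposed(kg, nr, d)["additions"])
}

#' Full cost report
#'
#' Bundles the compression ratio, fixed-rate and multirate operation counts
#' and their gain for a given configuration. An optional denoising term
#' (`denoise_taps` FIR taps over `denoise_samples` samples) can be reported
#' alongside as an extension; it is kept out of the fixed-vs-multirate
#' comparison.
#'
#' @param nr Samples per conventional window (default 360, a one-second
#'   window at 360 Hz).
#' @param p Features per instance (default 16).
#' @param kg Half-band filter taps (default 8, db4).
#' @param d Decimation factor (default 4, matching the printed multirate
#'   coefficient; the alias-safe pipeline default is 3).
#' @param denoise_taps,denoise_samples Optional denoising FIR extension.
#' @return An object of class `cost_report`.
#' @export
cost_report <- function(nr = 360, p = 16, kg = 8, d = 4,
                        denoise_taps = NULL, denoise_samples = NULL) {
  rep <- list(
    nr = nr, p = p, kg = kg, d = d,
    r_comp = compression_ratio(nr, p),
    fixed = complexity_fixed(kg, nr),
    proposed = complexity_proposed(kg, nr, d),
    gain = computational_gain(kg, nr, d)
  )
  if (!is.null(denoise_taps) && !is.null(denoise_samples)) {
    v <- denoise_taps * denoise_samples
    rep$denoise_extension <- c(additions = v, multiplications = v)
  }
  structure(rep, class = "cost_report")
}

#' @export
print.cost_report <- function(x, ...) {
  cat(sprintf("<cost_report> Nr=%g, P=%g, Kg=%g, D=%g\n", x$nr, x$p, x$kg, x$d))
  cat(sprintf("  compression ratio R_COMP = %g\n", x$r_comp))
  cat(sprintf("  fixed-rate: %g additions + %g multiplications\n",
              x$fixed["additions"], x$fixed["multiplications"]))
  cat(sprintf("  multirate:  %g additions + %g multiplications\n",
              x$proposed["additions"], x$proposed["multiplications"]))
  cat(sprintf("  gain = %g\n", x$gain))
  if (!is.null(x$denoise_extension)) {
    cat(sprintf("  (+ denoising extension: %g additions + %g multiplications, not compared)\n",
                x$denoise_extension["additions"], x$denoise_extension["multiplications"]))
  }
  invisible(x)
}
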