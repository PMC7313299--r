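# Synthetic three-class ECG beat generator.
#
# Beats are modelled as a sum of Gaussian bumps for the P, Q, R, S and T
# deflections (plus class-specific extras), which keeps the waveform smooth,
# band-limited and analytically peaked. The three classes encode their
# diagnostic morphology qualitatively:
#   N    - normal sinus beat (narrow QRS, upright T),
#   RBBB - right bundle branch block (widened QRS with a secondary R' bump
#          and discordant T),
#   WPW  - Wolff-Parkinson-White pre-excitation (delta wave sliding into R,
#          shortened PR interval).

.default_waves <- list(
  N = data.frame(
    wave = c("P", "Q", "R", "S", "T"),
    center_s = c(0.18, 0.42, 0.45, 0.48, 0.65),
    width_s = c(0.025, 0.010, 0.012, 0.010, 0.045),
    amplitude_mv = c(0.15, -0.12, 1.10, -0.25, 0.30),
    stringsAsFactors = FALSE
  ),
  RBBB = data.frame(
    wave = c("P", "Q", "R", "S", "R'", "T"),
    center_s = c(0.18, 0.41, 0.45, 0.50, 0.54, 0.70),
    width_s = c(0.025, 0.012, 0.018, 0.018, 0.020, 0.050),
    amplitude_mv = c(0.12, -0.10, 0.90, -0.35, 0.55, -0.18),
    stringsAsFactors = FALSE
  ),
  WPW = data.frame(
    wave = c("P", "delta", "R", "S", "T"),
    center_s = c(0.14, 0.39, 0.44, 0.48, 0.66),
    width_s = c(0.025, 0.030, 0.014, 0.012, 0.050),
    amplitude_mv = c(0.15, 0.40, 1.20, -0.30, 0.35),
    stringsAsFactors = FALSE
  )
)

#' Beat morphology template
#'
#' Returns the sum-of-Gaussians description of one beat of the requested
#' class, or validates a custom wave table. Each wave is a Gaussian bump with
#' a centre (s), a width (Gaussian sigma, s) and an amplitude (mV). Exactly
#' one wave must be named `"R"` and it must carry the largest absolute
#' amplitude.
#'
#' @param class_label One of `"N"`, `"RBBB"`, `"WPW"`.
#' @param waves Optional data frame with columns `wave`, `center_s`,
#'   `width_s`, `amplitude_mv`; defaults to the built-in morphology for
#'   `class_label`.
#' @param beat_len_s Beat duration in seconds (default 0.9).
#'
#' @return An object of class `beat_template`.
#' @examples
#' beat_template("RBBB")
#' @export
beat_template <- function(class_label = c("N", "RBBB", "WPW"),
                          waves = NULL, beat_len_s = 0.9) {
  class_label <- match.arg(class_label)
  if (is.null(waves)) waves <- .default_waves[[class_label]]
  stopifnot_scalar_pos(beat_len_s, "beat_len_s")
  needed <- c("wave", "center_s", "width_s", "amplitude_mv")
  if (!is.data.frame(waves) || !all(needed %in% names(waves))) {
    stop("`waves` must be a data frame with columns ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  if (any(waves$width_s <= 0)) {
    stop("all wave widths must be > 0", call. = FALSE)
  }
  if (beat_len_s <= max(waves$center_s)) {
    stop("`beat_len_s` must exceed the largest wave centre", call. = FALSE)
  }
  r <- which(waves$wave == "R")
  if (length(r) != 1L) {
    stop("exactly one wave must be designated \"R\"", call. = FALSE)
  }
  if (abs(waves$amplitude_mv[r]) < max(abs(waves$amplitude_mv))) {
    stop("the R wave must carry the largest |amplitude|", call. = FALSE)
  }
  structure(
    list(class_label = class_label, waves = waves,
         beat_len_s = as.numeric(beat_len_s)),
    class = "beat_template"
  )
}

#' @export
print.beat_template <- function(x, ...) {
  cat(sprintf("<beat_template> class %s, %d waves, %.2f s\n",
              x$class_label, nrow(x$waves), x$beat_len_s))
  print(x$waves, row.names = FALSE)
  invisible(x)
}

#' Noise model for synthetic records
#'
#' Additive contamination applied on top of a clean beat: a power-line
#' interference (PLI) sinusoid, a slow baseline-wander (BW) sinusoid, and
#' white Gaussian noise. Defaults are typical ambulatory contamination
#' levels; set all amplitudes to zero for clean beats.
#'
#' @param pli_amplitude_mv PLI amplitude in mV (default 0.2).
#' @param pli_freq_hz PLI frequency in Hz (default 50; set 60 for 60 Hz
#'   mains regions).
#' @param bw_amplitude_mv Baseline-wander amplitude in mV (default 0.3).
#' @param bw_freq_hz Baseline-wander frequency in Hz (default 0.3).
#' @param white_sigma_mv Standard deviation of white Gaussian noise in mV
#'   (default 0.05).
#'
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(pli_amplitude_mv = 0.2, pli_freq_hz = 50,
                       bw_amplitude_mv = 0.3, bw_freq_hz = 0.3,
                       white_sigma_mv = 0.05) {
  amps <- c(pli_amplitude_mv, bw_amplitude_mv, white_sigma_mv)
  if (any(!is.finite(amps)) || any(amps < 0)) {
    stop("noise amplitudes must be finite and >= 0", call. = FALSE)
  }
  if (!(bw_freq_hz > 0 && bw_freq_hz < pli_freq_hz)) {
    stop("need 0 < bw_freq_hz < pli_freq_hz", call. = FALSE)
  }
  structure(
    list(pli_amplitude_mv = pli_amplitude_mv, pli_freq_hz = pli_freq_hz,
         bw_amplitude_mv = bw_amplitude_mv, bw_freq_hz = bw_freq_hz,
         white_sigma_mv = white_sigma_mv),
    class = "noise_spec"
  )
}

# Evaluate a wave table at the sample times of one beat.
.eval_waves <- function(waves, t) {
  y <- numeric(length(t))
  for (i in seq_len(nrow(waves))) {
    y <- y + waves$amplitude_mv[i] *
      exp(-0.5 * ((t - waves$center_s[i]) / waves$width_s[i])^2)
  }
  y
}

#' Generate one clean beat from a template
#'
#' Deterministic: the waveform is the template's Gaussian bumps evaluated at
#' the sample times, with no noise and no jitter.
#'
#' @param template A [beat_template()].
#' @param fs Sampling rate in Hz.
#'
#' @return A [signal_record()] of `round(beat_len_s * fs)` samples, labelled
#'   with the template's class.
#' @examples
#' beat <- generate_beat(beat_template("N"), fs = 360)
#' length(beat$samples)  # 324
#' @export
generate_beat <- function(template, fs) {
  if (!inherits(template, "beat_template")) {
    stop("`template` must be a beat_template", call. = FALSE)
  }
  stopifnot_scalar_pos(fs, "fs")
  n <- round(template$beat_len_s * fs)
  if (n < 1L) stop("`fs` too low for this beat length", call. = FALSE)
  t <- (seq_len(n) - 1) / fs
  signal_record(.eval_waves(template$waves, t), fs = fs,
                label = template$class_label,
                source_id = paste0("template-", template$class_label))
}

#' Generate a labelled synthetic dataset
#'
#' Produces `n_per_class` beats for each of the three classes. Each record
#' gets per-record jitter of wave amplitudes and widths plus the additive
#' noise of `noise`. One master stream seeds an independent per-record
#' stream, indexed by the record's position, so output is bit-identical for
#' a given seed regardless of how records are later reordered.
#'
#' @param n_per_class Number of beats per class (>= 1).
#' @param fs Sampling rate in Hz (default 360).
#' @param noise A [noise_spec()]; default is the package's ambulatory
#'   contamination model.
#' @param seed Integer seed; mandatory.
#' @param classes Character vector of classes to generate (default all
#'   three).
#' @param jitter_sd Relative standard deviation of per-record amplitude and
#'   width jitter (default 0.05).
#'
#' @return A list of [signal_record()]s of length
#'   `length(classes) * n_per_class`, in class-major order.
#' @examples
#' ds <- generate_dataset(3, seed = 1)
#' length(ds)  # 9
#' table(vapply(ds, function(r) r$label, ""))
#' @export
generate_dataset <- function(n_per_class, fs = 360, noise = noise_spec(),
                             seed, classes = c("N", "RBBB", "WPW"),
                             jitter_sd = 0.05) {
  if (!is.numeric(n_per_class) || n_per_class < 1) {
    stop("`n_per_class` must be >= 1", call. = FALSE)
  }
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  if (!inherits(noise, "noise_spec")) {
    stop("`noise` must be a noise_spec", call. = FALSE)
  }
  if (noise$pli_freq_hz >= fs / 2) {
    stop("pli_freq_hz must be below fs/2", call. = FALSE)
  }
  n_per_class <- as.integer(n_per_class)
  n_total <- length(classes) * n_per_class
  record_seeds <- with_seed(seed, sample.int(2147483646L, n_total))
  templates <- lapply(classes, beat_template)
  out <- vector("list", n_total)
  r <- 0L
  for (ci in seq_along(classes)) {
    tpl <- templates[[ci]]
    n <- round(tpl$beat_len_s * fs)
    t <- (seq_len(n) - 1) / fs
    for (i in seq_len(n_per_class)) {
      r <- r + 1L
      out[[r]] <- with_seed(record_seeds[r], {
        w <- tpl$waves
        nw <- nrow(w)
        w$amplitude_mv <- w$amplitude_mv * (1 + stats::rnorm(nw, 0, jitter_sd))
        w$width_s <- w$width_s * pmax(0.2, 1 + stats::rnorm(nw, 0, jitter_sd))
        y <- .eval_waves(w, t)
        y <- y + noise$pli_amplitude_mv *
          sin(2 * pi * noise$pli_freq_hz * t + stats::runif(1, 0, 2 * pi))
        y <- y + noise$bw_amplitude_mv *
          sin(2 * pi * noise$bw_freq_hz * t + stats::runif(1, 0, 2 * pi))
        if (noise$white_sigma_mv > 0) {
          y <- y + stats::rnorm(n, 0, noise$white_sigma_mv)
        }
        signal_record(y, fs = fs, label = tpl$class_label,
                      source_id = sprintf("synth-%s-%04d", tpl$class_label, i))
      })
    }
  }
  out
}

#' Labels of a list of records
#'
#' @param records List of [signal_record()]s.
#' @return Character vector of labels (`NA` where unlabelled).
#' @export
dataset_labels <- function(records) {
  vapply(records, function(r) if (is.null(r$label)) NA_character_ else r$label,
         character(1))
}
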