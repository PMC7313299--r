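# Shared fixtures and independent oracles for the test suite.

zero_noise <- function() noise_spec(0, 50, 0, 0.3, 0)

# Full front end applied to a list of records: filter -> decimate -> segment.
preprocess_records <- function(records, d = 3, seg_len_s = 0.9,
                               spec = filter_spec()) {
  coeffs <- design_bandpass(spec)
  segs <- lapply(records, function(r) {
    segment_signal(decimate_signal(apply_filter(r, coeffs), d,
                                   fmax = spec$fc_high),
                   seg_len_s = seg_len_s)
  })
  do.call(c, segs)
}

# Memoised zero-noise 450-beat feature matrix (150 per class, fixed seed).
.fixture_env <- new.env(parent = emptyenv())
features_450_zero_noise <- function() {
  if (is.null(.fixture_env$fm450)) {
    ds <- generate_dataset(150, fs = 360, noise = zero_noise(), seed = 20260920)
    .fixture_env$fm450 <- build_feature_matrix(preprocess_records(ds))
  }
  .fixture_env$fm450
}

# Reference 3-level DWT via PyWavelets (periodization mode); one python
# call for a whole matrix of signals (rows).
pywt_wavedec3 <- function(xmat, order) {
  script <- test_path("pywt-wavedec3.py")
  fin <- tempfile(fileext = ".tsv")
  fout <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(fin, fout)))
  write.table(format(xmat, digits = 17, scientific = TRUE),
              fin, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  status <- system2("python", c(script, fin, fout, order))
  stopifnot(status == 0)
  as.matrix(read.table(fout, sep = ""))
}

# Brute-force KNN oracle: full distance sort, majority vote, summed-distance
# then lexicographic tie-break. Deliberately naive (per-element loops).
knn_oracle <- function(x, labels, q, k) {
  d <- numeric(nrow(x))
  for (i in seq_len(nrow(x))) d[i] <- sqrt(sum((x[i, ] - q)^2))
  ord <- order(d, seq_along(d))
  nb <- ord[seq_len(k)]
  counts <- table(labels[nb])
  best <- names(counts)[counts == max(counts)]
  if (length(best) > 1L) {
    sums <- vapply(best, function(cl) sum(d[nb][labels[nb] == cl]), numeric(1))
    best <- sort(best[sums == min(sums)])
  }
  best[1L]
}

# Two-sided DFT power fraction above a frequency (Hz).
power_fraction_above <- function(x, fs, f0) {
  p <- Mod(stats::fft(x))^2
  f <- (seq_along(x) - 1) * fs / length(x)
  sum(p[f > f0 & f < fs - f0]) / sum(p)
}

# DTFT magnitude at arbitrary frequencies, normalised by record length, so
# records of different rates/lengths over the same duration are comparable.
dtft_mag <- function(x, fs, f) {
  t <- (seq_along(x) - 1) / fs
  vapply(f, function(fi) Mod(sum(x * exp(-2i * pi * fi * t))) / length(x),
         numeric(1))
}

with_seed_labels <- function(labels, seed) {
  set.seed(seed)
  sample(labels)
}

random_feature_df <- function(n, seed, p = 16, classes = c("A", "B", "C")) {
  set.seed(seed)
  df <- as.data.frame(matrix(rnorm(n * p), n, p))
  names(df) <- paste0("f", seq_len(p))
  df$label <- sample(classes, n, replace = TRUE)
  df
}
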