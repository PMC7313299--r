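test_that("the band-pass design meets its linear-phase and response contract", {
  b <- design_bandpass(filter_spec())
  expect_length(b, 123)
  # exactly symmetric coefficients => linear phase
  expect_true(all(b == rev(b)))

  H <- filter_response(b, c(0, 10, 120), fs = 360)
  expect_gt(H[2], 0.95)   # passband gain at 10 Hz
  expect_lt(H[2], 1.05)
  expect_lt(H[3], 0.05)   # stopband at 120 Hz
  expect_lt(H[1], H[2])   # DC attenuated relative to the passband

  # symmetry holds across other specs too
  b2 <- design_bandpass(filter_spec(1, 40, order = 60, fs = 250))
  expect_lt(max(abs(b2 - rev(b2))), 1e-12)
})

test_that("filter specs violating the half-rate rule are rejected", {
  expect_error(filter_spec(fc_high = 200, fs = 360), "half the sampling rate")
  expect_error(filter_spec(fc_low = 60, fc_high = 50), "fc_low < fc_high")
  expect_error(filter_spec(order = 121), "even")
})

test_that("filtering compensates group delay and separates pass/stop bands", {
  b <- design_bandpass(filter_spec())
  # unit impulse comes back as the (delay-compensated) coefficient sequence
  imp <- numeric(400)
  imp[200] <- 1
  y <- apply_filter(signal_record(imp, 360), b)
  expect_length(y$samples, 400)
  expect_equal(y$samples[139:261], as.numeric(b), tolerance = 1e-12)

  rms <- function(v) sqrt(mean(v^2))
  core <- 124:(1080 - 123)  # discard one filter length at each edge
  t <- (0:1079) / 360
  pass <- sin(2 * pi * 10 * t)
  yp <- apply_filter(signal_record(pass, 360), b)$samples
  expect_lt(abs(rms(yp[core]) / rms(pass[core]) - 1), 0.05)

  stopb <- sin(2 * pi * 120 * t)
  ys <- apply_filter(signal_record(stopb, 360), b)$samples
  expect_lt(rms(ys[core]) / rms(stopb[core]), 0.05)

  expect_error(apply_filter(signal_record(rnorm(50), 360), b), "longer")
})

test_that("the alias-safety bound is fs over twice the band limit", {
  expect_equal(max_decimation_factor(360, 50), 3.6)
  expect_equal(max_decimation_factor(360, 90), 2.0)
  for (fs in c(100, 250, 360, 1000)) {
    expect_equal(max_decimation_factor(fs, fs / 2), 1.0)
  }
})

test_that("decimation keeps every D-th sample and guards the bound", {
  x <- signal_record(1:9, fs = 360)
  y <- decimate_signal(x, 3)
  expect_equal(y$samples, c(1, 4, 7))
  expect_equal(y$fs, 120)

  expect_identical(decimate_signal(x, 1)$samples, x$samples)

  expect_error(decimate_signal(x, 4), "3.6")
  forced <- decimate_signal(x, 4, force = TRUE)
  expect_equal(forced$samples, c(1, 5, 9))
  expect_equal(forced$fs, 90)
})

test_that("repeated decimation composes multiplicatively", {
  set.seed(10)
  x <- signal_record(rnorm(1000), fs = 360)
  for (a in 1:4) for (b in 1:3) {
    two <- decimate_signal(decimate_signal(x, a, force = TRUE), b, force = TRUE)
    one <- decimate_signal(x, a * b, force = TRUE)
    expect_identical(two$samples, one$samples)
    expect_equal(two$fs, one$fs)
  }
})

test_that("segmentation tiles rectangular windows and drops the remainder", {
  x <- signal_record(rnorm(1080), fs = 120, label = "N")
  segs <- segment_signal(x, 0.9)
  expect_length(segs, 10)
  expect_true(all(vapply(segs, function(s) length(s$samples), 0L) == 108))
  expect_identical(segs[[1]]$label, "N")
  expect_equal(segs[[1]]$t_center, (107 / 2) / 120)
  expect_equal(segs[[2]]$samples, x$samples[109:216])

  x90 <- signal_record(rnorm(200), fs = 90)
  expect_length(segment_signal(x90, 0.9)[[1]]$samples, 81)

  expect_warning(out <- segment_signal(signal_record(rnorm(100), 120), 0.9),
                 "shorter")
  expect_length(out, 0)

  # count invariant over random lengths
  set.seed(11)
  for (n in sample(108:2000, 5)) {
    s <- segment_signal(signal_record(rnorm(n), 120), 0.9)
    expect_length(s, n %/% 108)
  }
})

test_that("filtering then alias-safe decimation preserves the sub-band spectrum, unsafe decimation does not", {
  # band-limited beat with deliberate 40 Hz content
  t <- (0:1079) / 360
  beat <- rep(generate_beat(beat_template("N"), 360)$samples, length.out = 1080)
  x <- signal_record(beat + 0.3 * sin(2 * pi * 40 * t), fs = 360)
  xf <- apply_filter(x, design_bandpass(filter_spec()))

  f_lo <- 1:49
  ref <- dtft_mag(xf$samples, 360, f_lo)
  d3 <- decimate_signal(xf, 3)
  got3 <- dtft_mag(d3$samples, d3$fs, f_lo)
  expect_lt(sqrt(sum((got3 - ref)^2) / sum(ref^2)), 0.05)

  f_lo7 <- 1:24  # below the D=7 Nyquist of ~25.7 Hz
  ref7 <- dtft_mag(xf$samples, 360, f_lo7)
  d7 <- decimate_signal(xf, 7, force = TRUE)
  got7 <- dtft_mag(d7$samples, d7$fs, f_lo7)
  expect_gt(sqrt(sum((got7 - ref7)^2) / sum(ref7^2)), 0.05)
})
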