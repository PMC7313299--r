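test_that("Daubechies filters satisfy the half-band identities", {
  f1 <- daubechies_filters(1)
  expect_equal(f1$g, c(1, 1) / sqrt(2), tolerance = 1e-12)

  # db2 closed form
  s3 <- sqrt(3)
  expect_equal(daubechies_filters(2)$g,
               c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2)),
               tolerance = 1e-12)

  # db4 against the published coefficient table
  expect_equal(daubechies_filters(4)$g,
               c(0.23037781330885523, 0.71484657055254153,
                 0.63088076792959036, -0.02798376941698385,
                 -0.18703481171888114, 0.03084138183598697,
                 0.03288301166698295, -0.01059740178499728),
               tolerance = 1e-10)

  for (ord in 1:10) {
    f <- daubechies_filters(ord)
    expect_identical(f$Kg, 2L * ord)
    expect_length(f$g, f$Kg)
    expect_lt(abs(sum(f$g) - sqrt(2)), 1e-10)
    expect_lt(abs(sum(f$h)), 1e-10)
    # quadrature-mirror relation h_k = (-1)^k g_{Kg-1-k} (0-based)
    expect_equal(f$h, (-1)^(seq_len(f$Kg) - 1) * rev(f$g))
    # orthonormality under even shifts
    for (m in 1:(ord - 1 + (ord == 1))) {
      shifted <- c(rep(0, 2 * m), f$g)[seq_len(f$Kg)]
      expect_lt(abs(sum(f$g * shifted)), 1e-10)
    }
    expect_equal(sum(f$g^2), 1, tolerance = 1e-10)
  }

  expect_error(daubechies_filters(0), "1..10")
  expect_error(daubechies_filters(11), "1..10")
})

test_that("one analysis level treats constants and alternations as pure a and d", {
  haar <- daubechies_filters(1)
  lv <- dwt_level(rep(2.5, 16), haar)
  expect_equal(lv$a, rep(2.5 * sqrt(2), 8))
  expect_equal(lv$d, rep(0, 8))

  alt <- rep(c(1, -1), 8)
  lv2 <- dwt_level(alt, haar)
  expect_equal(lv2$a, rep(0, 8))
  expect_equal(abs(lv2$d), rep(sqrt(2), 8))

  expect_error(dwt_level(rnorm(9), haar), "even")
})

test_that("analysis and synthesis levels are mutual inverses for every order", {
  set.seed(21)
  for (ord in 1:10) {
    f <- daubechies_filters(ord)
    x <- rnorm(64)
    lv <- dwt_level(x, f)
    expect_length(lv$a, 32)
    expect_equal(idwt_level(lv$a, lv$d, f), x, tolerance = 1e-10)
    # orthonormality: energy is preserved
    expect_equal(sum(lv$a^2) + sum(lv$d^2), sum(x^2), tolerance = 1e-8)
  }
  expect_error(idwt_level(rnorm(4), rnorm(5), daubechies_filters(2)), "equal length")
})

test_that("the 3-level cascade obeys the padding and length contract", {
  seg <- ecg_segment(rnorm(108), fs_effective = 120, label = "N")
  dec <- decompose3(seg)
  expect_identical(dec$n_padded, 112L)
  expect_length(dec$d1, 56)
  expect_length(dec$d2, 28)
  expect_length(dec$d3, 14)
  expect_length(dec$a3, 14)
  expect_identical(dec$label, "N")

  expect_equal(dec$band_edges$a3, c(0, 7.5))
  expect_equal(dec$band_edges$d3, c(7.5, 15))
  expect_equal(dec$band_edges$d2, c(15, 30))
  expect_equal(dec$band_edges$d1, c(30, 60))

  z <- decompose3(numeric(81), fs_effective = 90)
  expect_true(all(c(z$d1, z$d2, z$d3, z$a3) == 0))

  expect_error(decompose3(numeric(0), fs_effective = 90), "empty")
})

test_that("three-level decomposition reconstructs perfectly and preserves energy", {
  set.seed(22)
  for (ord in 1:10) {
    for (n in c(81, 108, 100, 137)) {
      x <- rnorm(n)
      dec <- decompose3(x, order = ord, fs_effective = 120)
      expect_lt(max(abs(reconstruct3(dec) - x)), 1e-8)
      xpad <- c(x, numeric(dec$n_padded - n))
      expect_equal(sum(dec$d1^2) + sum(dec$d2^2) + sum(dec$d3^2) + sum(dec$a3^2),
                   sum(xpad^2), tolerance = 1e-8)
    }
  }

  z <- decompose3(numeric(16), fs_effective = 120)
  expect_identical(reconstruct3(z), numeric(16))
})

test_that("decompositions match the reference periodized DWT", {
  set.seed(23)
  xmat <- matrix(rnorm(10 * 108), 10, 108)
  for (ord in c(1, 2, 4)) {
    ref <- pywt_wavedec3(cbind(xmat, matrix(0, 10, 4)), ord)
    for (i in 1:10) {
      dec <- decompose3(xmat[i, ], order = ord, fs_effective = 120)
      expect_lt(max(abs(c(dec$a3, dec$d3, dec$d2, dec$d1) - ref[i, ])), 1e-8)
    }
  }
})
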