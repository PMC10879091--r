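test_that("prefix and suffix spectra match a brute-force DFT oracle", {
  set.seed(101)
  x <- rnorm(64)
  pad <- 128
  pre <- prefix_spectra(x, pad)
  suf <- suffix_spectra(x, pad)
  for (u in 0:63) {
    expect_lt(max(abs(pre[, u + 1] - brute_dft_onesided(x[1:(u + 1)], pad))), 1e-9)
    expect_lt(max(abs(suf[, u + 1] - brute_dft_onesided(x[(u + 1):64], pad))), 1e-9)
  }
})

test_that("spectra boundary columns and degenerate inputs behave", {
  set.seed(102)
  x <- rnorm(32)
  pad <- 64
  full <- Mod(stats::fft(c(x, numeric(32))))[1:33]
  pre <- prefix_spectra(x, pad)
  suf <- suffix_spectra(x, pad)
  expect_equal(pre[, 32], full, tolerance = 1e-12)  # prefix at u = n-1
  expect_equal(suf[, 1], full, tolerance = 1e-12)   # suffix at u = 0
  expect_true(all(prefix_spectra(numeric(16), 32) == 0))
  expect_true(all(suffix_spectra(numeric(16), 32) == 0))
  expect_error(prefix_spectra(x, 16), class = "fbft_parameter_error")
})

test_that("the fast path equals the literal reference implementation", {
  set.seed(103)
  for (n in c(2, 16, 57, 128)) {
    x <- rnorm(n)
    a <- fbft(x, fs = n)
    b <- fbft_reference(x, fs = n)
    expect_lt(max(abs(a$magnitude - b$magnitude)), 1e-12)
    expect_equal(a$freqs, b$freqs)
    expect_equal(a$times, b$times)
    expect_true(all(is.finite(b$magnitude)))
  }
})

test_that("stride thins the time grid without changing computed columns", {
  set.seed(104)
  x <- rnorm(100)
  ref <- fbft(x, fs = 100, stride = 1)
  thin <- fbft(x, fs = 100, stride = 7)
  us <- thin$meta$u
  expect_true(99 %in% us)                 # last index always evaluated
  expect_equal(thin$magnitude, ref$magnitude[, us + 1], tolerance = 0)
  expect_equal(thin$times, ref$times[us + 1])
})

test_that("an impulse is localized to exactly its own time column", {
  x <- numeric(32)
  m <- 11                                  # 0-based impulse index
  x[m + 1] <- 2.5
  tf <- fbft(x, fs = 32)
  # prefix contains the impulse only for u >= m, suffix only for u <= m:
  # the minimum is nonzero at u = m alone, where |FFT| of an impulse is flat.
  expect_equal(tf$magnitude[, m + 1], rep(2.5, nrow(tf$magnitude)),
               tolerance = 1e-12)
  expect_true(all(tf$magnitude[, -(m + 1)] == 0))
})

test_that("a full-record sinusoid yields a stable interior ridge", {
  fs <- 128
  f0 <- 12
  x <- sin(2 * pi * f0 * (0:255) / fs)
  tf <- fbft(x, fs = fs)
  bin <- fs / tf$meta$pad_len
  interior <- which(tf$meta$u > 0.1 * 256 & tf$meta$u < 0.9 * 256)
  for (j in interior) {
    peak <- tf$freqs[-1][which.max(tf$magnitude[-1, j])]
    expect_lt(abs(peak - f0), bin + 1e-9)
  }
})

test_that("minimum bound: the map never exceeds either contributing spectrum", {
  set.seed(105)
  x <- rnorm(80)
  tf <- fbft(x, fs = 80)
  pre <- prefix_spectra(x, tf$meta$pad_len)
  suf <- suffix_spectra(x, tf$meta$pad_len)
  expect_true(all(tf$magnitude <= pre + 1e-15))
  expect_true(all(tf$magnitude <= suf + 1e-15))
})

test_that("time reversal flips the map's time axis", {
  set.seed(106)
  x <- rnorm(64)
  a <- fbft(x, fs = 64)
  b <- fbft(rev(x), fs = 64)
  expect_lt(max(abs(b$magnitude - a$magnitude[, ncol(a$magnitude):1])), 1e-9)
})

test_that("the transform is absolutely homogeneous in amplitude", {
  set.seed(107)
  x <- rnorm(50)
  a <- fbft(x, fs = 50)
  for (c in c(3.7, -2)) {
    b <- fbft(c * x, fs = 50)
    expect_equal(b$magnitude, abs(c) * a$magnitude, tolerance = 1e-12)
  }
})

test_that("FFT magnitude is invariant under circular time shift", {
  # validation of the transform convention: a time shift only changes phase
  set.seed(108)
  x <- c(rnorm(48), numeric(16))          # zero-padded sequence
  base <- Mod(stats::fft(x))
  for (t0 in c(1, 5, 16)) {
    shifted <- c(utils::tail(x, t0), utils::head(x, length(x) - t0))
    expect_lt(max(abs(Mod(stats::fft(shifted)) - base)), 1e-9)
  }
})

test_that("per-length normalization rebalances prefix and suffix energies", {
  set.seed(109)
  x <- rnorm(60)
  raw <- fbft(x, fs = 60)
  nrm <- fbft(x, fs = 60, normalize = TRUE)
  n <- 60
  us <- raw$meta$u
  manual <- pmin(sweep(prefix_spectra(x, raw$meta$pad_len), 2, us + 1, "/"),
                 sweep(suffix_spectra(x, raw$meta$pad_len), 2, n - us, "/"))
  expect_equal(nrm$magnitude, unname(manual), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(nrm$meta$normalize)
})

test_that("ridge_frequencies finds the dominant non-DC ridge", {
  mag <- matrix(0, 5, 4)
  mag[3, ] <- 1
  tf <- tf_map(mag, freqs = c(0, 5, 10, 15, 20), times = 0:3,
               meta = list(transform = "test", fs = 40))
  expect_equal(ridge_frequencies(tf), 10)

  fs <- 100
  x <- sin(2 * pi * 10 * (0:199) / fs)
  tf2 <- fbft(x, fs = fs)
  expect_lt(abs(ridge_frequencies(tf2) - 10), fs / tf2$meta$pad_len + 1e-9)

  zero <- tf_map(matrix(0, 3, 3), c(0, 1, 2), 0:2,
                 meta = list(transform = "test", fs = 4))
  expect_warning(r <- ridge_frequencies(zero), "no ridge")
  expect_true(is.na(r))
  expect_error(ridge_frequencies(tf, c(10, 20)), class = "fbft_parameter_error")
})

test_that("top-k ridges report separated spectral peaks", {
  fs <- 500
  x <- sin(2 * pi * 10 * (0:999) / fs) + 0.8 * sin(2 * pi * 60 * (0:999) / fs)
  tf <- fbft(x, fs = fs, stride = 4)
  top2 <- ridge_frequencies(tf, k = 2)
  bin <- fs / tf$meta$pad_len
  expect_length(top2, 2L)
  expect_lt(min(abs(top2 - 10)), bin + 1e-9)
  expect_lt(min(abs(top2 - 60)), bin + 1e-9)
})
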