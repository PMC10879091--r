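test_that("csv reading preserves shape, names and values", {
  set.seed(11)
  s <- signal(matrix(rnorm(4 * 2560), 4), fs = 256,
              channel_names = c("TP9", "AF7", "AF8", "TP10"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_signal_csv(s, path)
  r <- read_signal(path, "csv", fs = 256)
  expect_equal(n_channels(r), 4L)
  expect_equal(n_samples(r), 2560L)
  expect_equal(duration(r), 10)
  expect_identical(r$channel_names, s$channel_names)
  expect_lt(max(abs(r$samples - s$samples) / pmax(abs(s$samples), 1e-12)), 1e-9)
})

test_that("csv without a sampling rate is a configuration error", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2", "3,4"), path)
  expect_error(read_signal(path, "csv"), class = "fbft_config_error")
  expect_s3_class(read_signal(path, "csv", fs = 10), "fbft_signal")
})

test_that("ragged csv and missing files are reported as such", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2", "3"), path)
  expect_error(read_signal(path, "csv", fs = 10), class = "fbft_format_error")
  expect_error(read_signal(file.path(tempdir(), "nope.csv"), "csv", fs = 10),
               class = "fbft_io_error")
})

test_that("wav round-trips a generated mono tone", {
  tone <- signal(0.8 * sin(2 * pi * 440 * (0:2999) / 3000), fs = 3000)
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(tone, path)
  r <- read_wav(path)
  expect_equal(n_channels(r), 1L)
  expect_equal(r$fs, 3000)
  expect_equal(n_samples(r), 3000L)
  expect_lt(max(abs(r$samples - tone$samples)), 1e-4)  # 16-bit quantization
})

test_that("wav round-trips multi-channel audio with interleaving intact", {
  set.seed(5)
  s <- signal(matrix(runif(2 * 500, -0.9, 0.9), 2), fs = 8000)
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(s, path)
  r <- read_wav(path)
  expect_equal(n_channels(r), 2L)
  expect_lt(max(abs(r$samples - s$samples)), 1e-4)
})

test_that("edf round-trips channel names in order and calibrated values", {
  set.seed(7)
  s <- signal(matrix(rnorm(2 * 512), 2) * 50, fs = 256,
              channel_names = c("TP9", "AF7"))
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(s, path)
  r <- read_signal(path, "edf")
  expect_identical(r$channel_names, c("TP9", "AF7"))
  expect_equal(r$fs, 256)
  # 16-bit quantization over the per-channel amplitude range
  tol <- (max(s$samples) - min(s$samples)) / 65000
  expect_lt(max(abs(r$samples - s$samples)), 2 * tol)
})

test_that("edf writer handles non-integer record layouts and flat channels", {
  s <- signal(matrix(c(rnorm(300), rep(1, 300)), 2, byrow = TRUE), fs = 128,
              channel_names = c("a", "flat"))
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(s, path)   # 300 samples at 128 Hz -> single-record file
  r <- read_edf(path)
  expect_equal(r$fs, 128)
  expect_equal(n_samples(r), 300L)
  expect_lt(max(abs(r$samples[2, ] - 1)), 1e-3)
})

test_that("clean_nans implements both policies and their edge rules", {
  finite <- signal(matrix(rnorm(20), 2), fs = 10)
  expect_identical(clean_nans(finite, "drop_samples")$samples, finite$samples)

  ten <- signal(matrix(c(0:3, NaN, 5:9), 1), fs = 10)
  expect_equal(n_samples(clean_nans(ten, "drop_samples")), 9L)

  lin <- clean_nans(signal(c(0, NaN, 2), fs = 1), "interpolate")
  expect_equal(as.vector(lin$samples), c(0, 1, 2))

  # boundary gaps extend the nearest finite value
  edge <- clean_nans(signal(c(NA, NA, 3, 4, NA), fs = 1), "interpolate")
  expect_equal(as.vector(edge$samples), c(3, 3, 3, 4, 4))

  # dropping removes the whole time index across channels
  two <- signal(rbind(c(1, NaN, 3), c(4, 5, 6)), fs = 1)
  expect_equal(clean_nans(two, "drop_samples")$samples, rbind(c(1, 3), c(4, 6)))

  all_bad <- signal(matrix(NaN, 1, 4), fs = 1)
  expect_error(clean_nans(all_bad, "drop_samples"),
               class = "fbft_empty_signal_error")
  expect_error(clean_nans(all_bad, "interpolate"),
               class = "fbft_empty_signal_error")
})

test_that("clean_nans is idempotent", {
  set.seed(3)
  m <- matrix(rnorm(60), 3)
  m[sample(length(m), 8)] <- NaN
  s <- signal(m, fs = 20)
  for (policy in c("drop_samples", "interpolate")) {
    once <- clean_nans(s, policy)
    expect_identical(clean_nans(once, policy)$samples, once$samples)
  }
})

test_that("segmentation produces the closed-form window count and starts", {
  s <- signal(matrix(seq_len(2560), 1), fs = 256)  # 10 s
  wins <- segment(s, segment_spec(1, 0.25))
  expect_length(wins, floor((10 - 1) / 0.75) + 1)  # 13
  expect_equal(vapply(wins, `[[`, 0, "t0"), 0.75 * (0:12))
  expect_true(all(vapply(wins, n_samples, 0L) == 256L))

  expect_length(segment(s, segment_spec(10, 0)), 1L)
  expect_error(segment_spec(1, 1), class = "fbft_type_error")
  expect_warning(out <- segment(signal(1:10, fs = 10), segment_spec(2, 0)),
                 "longer than signal")
  expect_length(out, 0L)
})

test_that("non-overlapping windows concatenate back to the signal prefix", {
  set.seed(9)
  s <- signal(matrix(rnorm(2 * 1037), 2), fs = 100)
  wins <- segment(s, segment_spec(0.8, 0))
  recon <- do.call(cbind, lapply(wins, `[[`, "samples"))
  expect_identical(recon, s$samples[, seq_len(ncol(recon)), drop = FALSE])
  expect_equal(ncol(recon), length(wins) * 80L)
})
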