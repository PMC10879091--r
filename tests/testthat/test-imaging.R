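make_tf <- function(mag, fs = 100) {
  tf_map(mag, freqs = seq(0, fs / 2, length.out = nrow(mag)),
         times = seq(0, 1, length.out = ncol(mag)),
         meta = list(transform = "test", fs = fs))
}

test_that("rendering normalizes, orients and resizes as specified", {
  # constant map -> all-zero image (min = max rule)
  flat <- render_tf(make_tf(matrix(3, 8, 8)), render_spec(NULL))
  expect_true(all(flat == 0))

  # single maximal cell -> brightest pixel at that cell, frequency upward
  m <- matrix(0, 10, 12)
  m[3, 5] <- 7                     # freq row 3 (low), time col 5
  img <- render_tf(make_tf(m), render_spec(NULL))
  expect_equal(dim(img), c(10L, 12L))
  expect_equal(which(img == max(img), arr.ind = TRUE)[1, ],
               c(row = 10L - 3L + 1L, col = 5L))   # flipped vertically
  expect_equal(max(img), 1)

  sized <- render_tf(make_tf(matrix(runif(64), 8)), render_spec(c(224, 224)))
  expect_equal(dim(sized), c(224L, 224L))
  expect_true(all(sized >= 0 & sized <= 1))
})

test_that("rendering is monotone, with and without log compression", {
  set.seed(31)
  m <- matrix(runif(48, 0, 100), 6)
  for (log_scale in c(FALSE, TRUE)) {
    img <- render_tf(make_tf(m), render_spec(NULL, log_scale = log_scale))
    v <- as.vector(img[nrow(img):1, ])   # undo the vertical flip
    expect_equal(order(v), order(as.vector(m)))
  }
})

test_that("cubic resize honors the three CNN input geometries exactly", {
  set.seed(32)
  img <- matrix(runif(50 * 40), 50)
  for (g in list(c(256, 256), c(224, 224), c(227, 227))) {
    out <- resize_bicubic(img, g)
    expect_equal(dim(out), as.integer(g))
    arr <- resize_bicubic(array(runif(50 * 40 * 3), c(50, 40, 3)), g)
    expect_equal(dim(arr), c(as.integer(g), 3L))
  }
  # interpolation is exact on a constant image and preserves [0,1]
  expect_equal(resize_bicubic(matrix(0.4, 10, 10), c(23, 17)),
               matrix(0.4, 23, 17), tolerance = 1e-12)
})

test_that("compose_channels implements the rgb and concat rules", {
  a <- matrix(runif(30), 5)
  one <- compose_channels(list(a), "rgb")
  expect_equal(one$pixels[, , 1], a)
  expect_true(all(one$pixels[, , 2:3] == 0))

  three <- compose_channels(list(a, a, a), "rgb")
  expect_equal(three$pixels[, , 1], three$pixels[, , 2])  # gray composite
  expect_equal(three$pixels[, , 2], three$pixels[, , 3])

  four <- compose_channels(rep(list(a), 4), "concat",
                           channel_names = paste0("c", 1:4))
  expect_equal(dim(four$pixels), c(20L, 6L, 3L))           # height 4h
  expect_equal(four$pixels[, , 1], four$pixels[, , 3])
  expect_equal(four$provenance$channels, paste0("c", 1:4))

  expect_error(compose_channels(rep(list(a), 4), "rgb"), "concat",
               class = "fbft_parameter_error")
  expect_error(compose_channels(list(a, matrix(0, 2, 2)), "rgb"),
               class = "fbft_parameter_error")
})

test_that("chunk checksums match the reference CRC-32", {
  # expected values computed independently with zlib.crc32
  expect_equal(fbft:::crc32(charToRaw("123456789")), 3421780262)
  # long input exercising high-bit intermediate states (R integers cannot
  # represent 0x80000000, so the implementation works in doubles)
  expect_equal(fbft:::crc32(as.raw(rep(0:255, 37))), 2544663797)
})

test_that("write_png emits well-formed, deterministic PNG bytes", {
  set.seed(33)
  px <- array(runif(20 * 30 * 3), c(20, 30, 3))
  p1 <- withr::local_tempfile(fileext = ".png")
  p2 <- withr::local_tempfile(fileext = ".png")
  write_png(px, p1)
  write_png(px, p2)
  expect_equal(png_dims(p1), c(height = 20, width = 30))
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  expect_error(write_png(array(2, c(2, 2, 3)), p1), class = "fbft_parameter_error")
})

test_that("export_dataset writes one image per window plus a manifest", {
  set.seed(34)
  s <- signal(matrix(rnorm(2 * 2560), 2), fs = 256,
              channel_names = c("TP9", "AF7"))   # 10 s
  out <- withr::local_tempdir()
  man <- export_dataset(s, seg = segment_spec(1, 0.25),
                        transform_args = list(stride = 16),
                        render = render_spec(c(32, 32)), out_dir = out)
  expect_equal(nrow(man), 13L)
  pngs <- list.files(out, pattern = "\\.png$")
  expect_length(pngs, 13L)
  expect_identical(sort(man$file), sort(pngs))
  expect_true(all(man$height == 32L & man$width == 32L))
  expect_equal(man$start_s, 0.75 * (0:12))
  expect_true(file.exists(file.path(out, "manifest.json")))
})

test_that("export is deterministic: rerun gives byte-identical outputs", {
  set.seed(35)
  s <- signal(matrix(rnorm(4 * 512), 4), fs = 256,
              channel_names = c("a", "b", "c", "d"))
  run <- function() {
    out <- withr::local_tempdir(.local_envir = parent.frame())
    export_dataset(s, seg = segment_spec(1, 0), mode = "concat",
                   transform_args = list(stride = 16),
                   render = render_spec(c(28, 28)), out_dir = out)
    out
  }
  o1 <- run()
  o2 <- run()
  for (f in list.files(o1)) {
    expect_identical(readBin(file.path(o1, f), "raw", file.size(file.path(o1, f))),
                     readBin(file.path(o2, f), "raw", file.size(file.path(o2, f))),
                     label = f)
  }
})

test_that("four channels cannot be packed into rgb but concat succeeds", {
  set.seed(36)
  s <- signal(matrix(rnorm(4 * 512), 4), fs = 256)
  out <- withr::local_tempdir()
  expect_error(
    export_dataset(s, seg = segment_spec(1, 0), mode = "rgb",
                   transform_args = list(stride = 32),
                   render = render_spec(c(16, 16)), out_dir = out),
    "concat", class = "fbft_parameter_error")
  man <- export_dataset(s, seg = segment_spec(1, 0), mode = "concat",
                        transform_args = list(stride = 32),
                        render = render_spec(c(16, 16)), out_dir = out)
  expect_equal(nrow(man), 2L)
  expect_true(all(man$mode == "concat"))
})

test_that("an over-long window yields an empty manifest with a warning", {
  s <- signal(matrix(rnorm(100), 1), fs = 100)
  out <- withr::local_tempdir()
  expect_warning(
    expect_warning(
      man <- export_dataset(s, seg = segment_spec(5, 0),
                            render = render_spec(c(16, 16)), out_dir = out),
      "longer than signal"),
    "empty manifest")
  expect_equal(nrow(man), 0L)
})

test_that("tf maps round-trip through the JSON container", {
  set.seed(37)
  tf <- fbft(rnorm(40), fs = 40, stride = 4)
  path <- withr::local_tempfile(fileext = ".tfmap.json")
  write_tf_map(tf, path)
  back <- read_tf_map(path)
  # decimal JSON serialization round-trips to ~1e-15 relative, not bitwise
  expect_equal(back$magnitude, tf$magnitude, tolerance = 1e-12)
  expect_equal(back$freqs, tf$freqs)
  expect_equal(back$times, tf$times)
  expect_equal(back$meta$transform, "fbft")
})
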