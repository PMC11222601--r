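test_that("sequence construction enforces its invariants", {
  frames <- array(runif(2 * 4 * 5), c(2, 4, 5))
  s <- dsa_sequence(frames, fps = 6)
  expect_s3_class(s, "dsa_sequence")
  expect_equal(frame_times(s), c(0, 1 / 6))
  expect_error(dsa_sequence(frames[1, , , drop = FALSE], 6), "at least 2")
  expect_error(dsa_sequence(frames, fps = 0), "positive")
  bad <- frames; bad[1, 1, 1] <- NA
  expect_error(dsa_sequence(bad, 6), "finite")
})

test_that("frame timing covers {0, 1/fps, ..., (T-1)/fps} exactly", {
  s <- dsa_sequence(array(0:(9 * 4 - 1), c(9, 2, 2)), fps = 7.5)
  expect_identical(frame_times(s), (0:8) / 7.5)
})

test_that("TIFF save/load round trip is bit-identical for phantoms", {
  ph <- cached_phantom(noise_sigma = 2, seed = 3)
  d <- withr::local_tempdir()
  f <- file.path(d, "seq.tif")
  save_sequence(ph$sequence, f)
  back <- load_sequence(f)
  expect_identical(back$frames, ph$sequence$frames)
  expect_identical(back$fps, ph$sequence$fps)
  expect_identical(back$polarity_inverted, ph$sequence$polarity_inverted)
  # re-saving a loaded sequence is stable too
  f2 <- file.path(d, "again.tif")
  save_sequence(back, f2)
  expect_identical(load_sequence(f2)$frames, back$frames)
})

test_that("save_sequence refuses invalid sequences and bad paths", {
  ph <- cached_phantom()
  expect_error(save_sequence(ph$sequence, file.path(tempdir(), "no", "x.tif")),
               "does not exist")
  one <- ph$sequence
  one$frames <- one$frames[1, , , drop = FALSE]
  expect_error(dsa_sequence(one$frames, 6), "at least 2")
})

test_that("a TIFF stack loads with the expected geometry and fps override", {
  d <- withr::local_tempdir()
  f <- file.path(d, "stack.tif")
  frames <- lapply(1:10, function(k) matrix(runif(64 * 64), 64))
  tiff::writeTIFF(frames, f, bits.per.sample = 16L, compression = "none")
  s <- load_sequence(f, fps_override = 6)
  expect_equal(dim(s)[1], 10)
  expect_equal(dim(s)[2:3], c(64, 64))
  expect_equal(s$fps, 6)
  expect_equal(load_sequence(f)$fps, 6)  # default fps without metadata
})

test_that("directory frames load in lexicographic name order", {
  d <- withr::local_tempdir()
  # write constant frames whose level encodes the intended order
  lv <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 0.95, 0.99, 1.0)
  for (k in seq_along(lv))
    png::writePNG(matrix(lv[k], 8, 8), file.path(d, sprintf("f%02d.png", k - 1)))
  s <- load_sequence(d, fps_override = 6)
  expect_equal(dim(s)[1], 12)
  got <- vapply(1:12, function(k) s$frames[k, 1, 1], numeric(1))
  expect_equal(order(got), 1:12)  # name order == time order (rising levels)
})

test_that("mismatched frame sizes and missing files are rejected", {
  d <- withr::local_tempdir()
  png::writePNG(matrix(0.5, 8, 8), file.path(d, "a.png"))
  png::writePNG(matrix(0.5, 9, 8), file.path(d, "b.png"))
  expect_error(load_sequence(d, 6), "mismatched")
  expect_error(load_sequence(file.path(d, "nope.tif")), "no such file")
  writeLines("not a tiff", file.path(d, "junk.tif"))
  expect_error(load_sequence(file.path(d, "junk.tif")), "TIFF")
})

test_that("dark-contrast material is polarity-inverted on load", {
  ph <- generate_phantom(small_spec(noise_sigma = 0))
  inv <- max(ph$sequence$frames) - ph$sequence$frames  # iodine dark
  d <- withr::local_tempdir()
  f <- file.path(d, "dark.tif")
  tiff::writeTIFF(lapply(seq_len(dim(inv)[1]), function(k)
    inv[k, , ] / max(inv)), f, bits.per.sample = 16L, compression = "none")
  s <- load_sequence(f, fps_override = 6)
  expect_true(s$polarity_inverted)
  # after normalization the strongest-changing pixels brighten over time
  pix <- which(ph$vessel_mask, arr.ind = TRUE)[1, ]
  y <- s$frames[, pix[1], pix[2]]
  expect_gt(max(y) - y[1], 0)
})

test_that("multi-frame DICOM loads with frame rate from metadata", {
  d <- withr::local_tempdir()
  set.seed(42)
  frames <- lapply(1:6, function(k) matrix(sample.int(4000, 80, TRUE), 8, 10))
  f <- file.path(d, "seq.dcm")
  write_test_dicom(f, frames, cine_rate = 6)
  s <- load_sequence(f)
  expect_equal(dim(s), c(6L, 8L, 10L))
  expect_equal(s$fps, 6)
  # FrameTime fallback (ms per frame)
  f2 <- file.path(d, "ft.dcm")
  write_test_dicom(f2, frames, frame_time_ms = 250)
  expect_equal(load_sequence(f2)$fps, 4)
  # pixel values survive (up to the polarity decision, none needed here:
  # make a rising sequence and check a known pixel)
  rising <- lapply(1:6, function(k) matrix(100L * k, 4, 4))
  f3 <- file.path(d, "rise.dcm")
  write_test_dicom(f3, rising, cine_rate = 6)
  s3 <- load_sequence(f3)
  expect_equal(s3$frames[, 2, 2], 100 * (1:6))
})

test_that("color DICOM is rejected", {
  d <- withr::local_tempdir()
  frames <- lapply(1:3, function(k) matrix(1L, 4, 4))
  f <- file.path(d, "rgb.dcm")
  write_test_dicom(f, frames, cine_rate = 6, photometric = "RGB")
  expect_error(load_sequence(f), "grayscale")
})

test_that("score tables parse, validate ranges and reject duplicates", {
  d <- withr::local_tempdir()
  f <- file.path(d, "scores.csv")
  writeLines(c("case_id,score_dsa,score_combined",
               "c1,5,5", "c2,4,5", "c3,3,4"), f)
  tab <- load_scores(f)
  expect_s3_class(tab, "paired_scores")
  expect_equal(nrow(tab), 3)
  expect_equal(tab$score_combined, c(5L, 5L, 4L))

  writeLines(c("case_id,score_dsa,score_combined", "c1,6,5"), f)
  expect_error(load_scores(f), "outside 1-5.*row 1")
  writeLines(c("case_id,score_dsa,score_combined", "c1,5,5", "c1,4,4"), f)
  expect_error(load_scores(f), "duplicate")
  writeLines("case_id,score_dsa", f)
  expect_error(load_scores(f), "missing column")
})

test_that("the packaged bleeding fixture has one row per reported patient", {
  fx <- clinical_fixtures()
  expect_equal(nrow(fx$bleeding), 101)
  expect_equal(nrow(fx$no_bleeding), 34)
  expect_equal(nrow(fx$ex_vivo), 22)
})
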