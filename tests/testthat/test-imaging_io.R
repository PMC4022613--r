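# imaging_io: frame readers, ROI files, rasterization, pixel extraction

test_that("PNG read is an identity for 8-bit grayscale and is lossless", {
  withr_tmp <- tempfile(fileext = ".png")
  f <- echo_frame(matrix(77L, 24, 24))
  write_frame_png(f, withr_tmp)
  g <- read_frame(withr_tmp)
  expect_identical(g$pixels, f$pixels)
  expect_equal(g$bit_depth, 8L)

  set.seed(41)
  f2 <- echo_frame(matrix(sample(0:255, 40 * 32, TRUE), 40, 32))
  write_frame_png(f2, withr_tmp)
  expect_identical(read_frame(withr_tmp)$pixels, f2$pixels)
  # single-frame formats reject nonzero frame index
  expect_error(read_frame(withr_tmp, frame_index = 1), "frame index")
})

test_that("color PNG is converted to BT.601 luma grayscale", {
  p <- tempfile(fileext = ".png")
  arr <- array(0, dim = c(20, 20, 3))
  arr[, , 1] <- 1   # pure red
  png::writePNG(arr, p)
  f <- read_frame(p)
  expect_true(all(f$pixels == as.integer(round(0.299 * 255))))
})

test_that("deep inputs are rejected without rescale and rescaled with it", {
  # 16-bit path exercised via PGM with maxval 65535 (text format)
  p <- tempfile(fileext = ".pgm")
  ramp <- matrix(as.integer(seq(0, 65535, length.out = 32 * 32)), 32, 32)
  writeLines(c("P2", "32 32", "65535",
               apply(ramp, 1, paste, collapse = " ")), p)
  expect_error(read_frame(p), "bit depth")
  f <- suppressWarnings(read_frame(p, rescale = TRUE))
  # independent min-max rescale of the raw array
  expect_identical(f$pixels,
                   matrix(as.integer(round((ramp - min(ramp)) /
                                             diff(range(ramp)) * 255)),
                          32, 32))
  expect_warning(read_frame(p, rescale = TRUE), "rescal")
})

test_that("PGM P2/P5 round-trips and JPEG reads", {
  set.seed(7)
  px <- matrix(sample(0:255, 24 * 24, TRUE), 24, 24)
  p2 <- tempfile(fileext = ".pgm")
  write_frame_pgm(echo_frame(px), p2)
  expect_identical(read_frame(p2)$pixels, px)
  # binary P5 written by hand
  p5 <- tempfile(fileext = ".pgm")
  con <- file(p5, "wb")
  writeLines(c("P5", "24 24", "255"), con)
  writeBin(as.raw(as.vector(t(px))), con)
  close(con)
  expect_identical(read_frame(p5)$pixels, px)
  # JPEG is readable (lossy: assert proximity, not identity)
  pj <- tempfile(fileext = ".jpg")
  jpeg::writeJPEG(matrix(128 / 255, 32, 32), pj, quality = 0.95)
  expect_lt(max(abs(read_frame(pj)$pixels - 128)), 6)
})

test_that("DICOM round-trips, addresses frames, and rejects junk", {
  f1 <- echo_frame(matrix(10L, 20, 24), source_id = "a")
  set.seed(5)
  f2 <- echo_frame(matrix(sample(0:255, 20 * 24, TRUE), 20, 24))
  p <- tempfile(fileext = ".dcm")
  write_dicom(list(f1, f2), p)
  expect_identical(read_frame(p, frame_index = 0)$pixels, f1$pixels)
  expect_identical(read_frame(p, frame_index = 1)$pixels, f2$pixels)
  expect_error(read_frame(p, frame_index = 2), "frame index out of range")
  bad <- tempfile()
  writeLines("not an image", bad)
  expect_error(read_frame(bad), "unreadable|unrecognized")
  expect_error(read_frame(tempfile(fileext = ".png")), "unreadable")
})

test_that("frame invariants are enforced", {
  expect_error(echo_frame(matrix(300L, 20, 20)), "\\[0, 255\\]")
  expect_error(echo_frame(matrix(0L, 8, 20)), "16x16")
})

test_that("ROI JSON files round-trip and validate", {
  r1 <- roi("myocardial", cbind(c(5, 5, 15, 15), c(5, 25, 25, 5)))
  r2 <- roi("pericardial", cbind(c(30, 30, 40), c(5, 25, 15)))
  p <- tempfile(fileext = ".json")
  write_roi_file(list(r1, r2), p)
  back <- read_roi_file(p)
  expect_length(back, 2)
  expect_identical(back[[1]]$label, "myocardial")
  expect_identical(back[[2]]$label, "pericardial")
  expect_equal(back[[1]]$vertices, r1$vertices)
  expect_equal(back[[2]]$vertices, r2$vertices)

  writeLines('[{"label":"epicardial","vertices":[[0,0],[0,5],[5,0]]}]', p)
  expect_error(read_roi_file(p), "unknown label")
  writeLines('[{"label":"myocardial","vertices":[[0,0],[0,5]]}]', p)
  expect_error(read_roi_file(p), "3 vertices")
})

test_that("ROI constructor rejects degenerate and tangled polygons", {
  expect_error(roi("myocardial", cbind(c(0, 1, 2), c(0, 1, 2))),
               "degenerate polygon")
  # bow-tie
  expect_error(roi("myocardial", cbind(c(0, 10, 0, 10), c(0, 10, 10, 0))),
               "self-intersecting")
})

test_that("rectangle rasterization has the exact pixel count", {
  f <- echo_frame(matrix(0L, 64, 64))
  r <- roi("pericardial", cbind(c(10, 10, 19, 19), c(10, 19, 19, 10)))
  mask <- rasterize_roi(r, f)
  expect_equal(sum(mask), 100)
  expect_true(all(which(mask, arr.ind = TRUE) >= 11) &&
                all(which(mask, arr.ind = TRUE) <= 20))
})

test_that("triangle rasterization matches the exhaustive oracle", {
  f <- echo_frame(matrix(0L, 16, 16))
  v <- cbind(c(0, 0, 4), c(0, 4, 0))
  mask <- rasterize_roi(roi("myocardial", v), f, min_pixels = 1L)
  expect_identical(mask, oracle_rasterize(v, 16, 16))
})

test_that("rasterization equals the oracle on random simple polygons", {
  set.seed(100)
  f <- echo_frame(matrix(0L, 64, 64))
  for (i in 1:40) {
    v <- random_simple_polygon(12L, 64L, 64L)
    r <- tryCatch(roi("myocardial", v), error = function(e) NULL)
    if (is.null(r)) next    # rare degenerate draw
    mask <- rasterize_roi(r, f, min_pixels = 0L)
    expect_identical(mask, oracle_rasterize(v, 64, 64),
                     label = paste("polygon", i))
  }
})

test_that("mask minimum pixel count is enforced", {
  f <- echo_frame(matrix(0L, 64, 64))
  r <- roi("pericardial", cbind(c(10, 10, 12, 12), c(10, 12, 12, 10)))
  expect_error(rasterize_roi(r, f, min_pixels = 32L), "below the configured")
  expect_equal(sum(rasterize_roi(r, f, min_pixels = 9L)), 9)
})

test_that("extract_pixels matches a brute-force gather and is rotation invariant", {
  set.seed(11)
  px <- matrix(sample(0:255, 64 * 64, TRUE), 64, 64)
  f <- echo_frame(px)
  v <- cbind(c(5, 8, 20, 25, 12), c(10, 30, 34, 15, 5))
  s <- extract_pixels(f, roi("pericardial", v))
  mask <- oracle_rasterize(v, 64, 64)
  gathered <- integer(0)
  for (r in 1:64) for (c in 1:64) if (mask[r, c])
    gathered <- c(gathered, px[r, c])
  expect_equal(sort(s$intensities), sort(gathered))
  expect_equal(s$n, sum(mask))
  # rotate the vertex list: same polygon, same multiset
  for (k in 1:4) {
    vr <- v[c((k + 1):5, 1:k)[1:5], , drop = FALSE]
    sr <- extract_pixels(f, roi("pericardial", vr))
    expect_equal(sort(sr$intensities), sort(s$intensities))
  }
})

test_that("extract_pixels trivia: constant frame and checkerboard", {
  f <- echo_frame(matrix(42L, 32, 32))
  s <- extract_pixels(f, roi("myocardial",
                             cbind(c(4, 4, 20, 20), c(4, 20, 20, 4))))
  expect_true(all(s$intensities == 42L))

  cb <- matrix(0L, 32, 32)
  cb[(row(cb) + col(cb)) %% 2 == 0] <- 255L
  f2 <- echo_frame(cb)
  s2 <- extract_pixels(f2, roi("myocardial",
                               cbind(c(0, 0, 31, 31), c(0, 31, 31, 0))))
  expect_equal(sum(s2$intensities == 0), sum(s2$intensities == 255))
})
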