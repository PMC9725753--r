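test_that("stack write/read roundtrips pixels, roles and calibration", {
  px <- array(runif(2 * 1 * 2 * 20 * 30, 0, 900), c(2, 1, 2, 20, 30))
  cal <- Calibration(pixelSize = 0.05, zStep = 0.25, frameInterval = 2)
  s <- ImageStack(px, channelRoles = c("mito", "er"), calibration = cal)
  path <- file.path(tempdir(), "rt.tif")
  writeStack(s, path)
  s2 <- readStack(path)
  expect_equal(s2@pixels, s@pixels, tolerance = 1e-6)
  expect_identical(channelRoles(s2), c("mito", "er"))
  expect_equal(pixelSize(s2), 0.05)
  expect_equal(zStep(s2), 0.25)
  expect_equal(frameInterval(s2), 2)
  expect_equal(nFrames(s2), 2L)
  expect_equal(nChannels(s2), 2L)
})

test_that("reading errors are explicit", {
  expect_error(readStack(file.path(tempdir(), "no-such-file.tif")),
               "not found")
})

test_that("a plain TIFF without sidecar falls back to defaults with warning", {
  path <- file.path(tempdir(), "plain.tif")
  tiff::writeTIFF(matrix(runif(100), 10, 10), path, bits.per.sample = 32L)
  expect_warning(s <- readStack(path), "sidecar")
  expect_equal(pixelSize(s), 0.1)
  expect_identical(channelRoles(s), "mito")
})

test_that("micrometre ROI sizes convert to the expected pixel counts", {
  idx <- roiToPixels(ROI(c(1L, 1L), 15), Calibration(pixelSize = 0.1))
  expect_length(idx$rows, 150L)
  expect_length(idx$cols, 150L)
  ## um -> px -> um stays within one pixel
  for (sz in c(3.14, 7.5, 12.3)) {
    n <- length(roiToPixels(ROI(c(1L, 1L), sz), Calibration())$rows)
    expect_lt(abs(n * 0.1 - sz), 0.1)
  }
})

test_that("cropRoi extracts the exact sub-array and preserves calibration", {
  px <- array(seq_len(1 * 1 * 1 * 40 * 40), c(1, 1, 1, 40, 40))
  s <- ImageStack(px, "mito")
  crop <- cropRoi(s, ROI(c(5L, 9L), 2))       # 20 x 20 px
  expect_equal(dim(crop@pixels)[4:5], c(20L, 20L))
  expect_equal(crop@pixels[1, 1, 1, , ], px[1, 1, 1, 5:24, 9:28],
               ignore_attr = TRUE)
  expect_equal(pixelSize(crop), pixelSize(s))
  ## whole-image ROI is the identity
  whole <- cropRoi(s, ROI(c(1L, 1L), 4))
  expect_equal(whole@pixels, s@pixels, ignore_attr = TRUE)
  expect_error(cropRoi(s, ROI(c(30L, 30L), 2)), "outside")
})

test_that("invalid containers are rejected by validity checks", {
  expect_error(Calibration(pixelSize = -1), "positive")
  expect_error(ImageStack(array(-1, c(1, 1, 1, 4, 4)), "mito"))
  expect_error(ImageStack(array(0, c(1, 1, 2, 4, 4)), c("mito", "bogus")))
})
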