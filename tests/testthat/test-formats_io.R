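test_that("MRC files round-trip in every supported mode", {
  set.seed(21)
  img <- matrix(rnorm(64 * 64, sd = 10), 64)
  f <- tempfile(fileext = ".mrc")
  write_mrc(img, f, mode = 2)
  back <- read_micrograph(f)
  expect_equal(dim(back), c(64, 64))
  expect_equal(unclass(back)[, ], img, tolerance = 1e-6,
               ignore_attr = TRUE)
  # integer modes round to the stored precision
  imgi <- matrix(sample(-100:100, 48 * 48, replace = TRUE), 48)
  for (mode in c(0, 1)) {
    write_mrc(imgi, f, mode = mode)
    backi <- read_micrograph(f)
    expect_equal(unclass(backi)[, ], imgi, ignore_attr = TRUE)
  }
  unlink(f)
})

test_that("MRC header convention maps nx, ny to (rows = ny, cols = nx)", {
  set.seed(22)
  img <- matrix(rnorm(80 * 100), nrow = 80, ncol = 100)  # ny=80, nx=100
  f <- tempfile(fileext = ".mrc")
  write_mrc(img, f)
  hdr <- readBin(f, "integer", n = 2, size = 4, endian = "little")
  expect_equal(hdr, c(100L, 80L))  # nx, ny
  expect_equal(dim(read_micrograph(f)), c(80L, 100L))
  unlink(f)
})

test_that("an independent MRC reader agrees on the same fixture", {
  # cross-check the byte layout against gemmi's CCP4/MRC map reader
  set.seed(23)
  img <- matrix(round(rnorm(40 * 56), 4), nrow = 40, ncol = 56)
  f <- tempfile(fileext = ".mrc")
  write_mrc(img, f)
  script <- paste(
    "import gemmi, sys",
    sprintf("m = gemmi.read_ccp4_map('%s')", f),
    "a = m.grid",
    "print(a.nu, a.nv, a.nw)",
    "print(repr(round(a.get_value(3, 5, 0), 4)))", sep = "; ")
  out <- suppressWarnings(system2("python", c("-c", shQuote(script)),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (is.null(status)) {
    expect_equal(out[1], "56 40 1")  # nx (fast axis) = cols, ny = rows
    # gemmi indexes (u, v, w) = (x, y, z); x=3, y=5 -> R img[6, 4]
    expect_equal(as.numeric(out[2]), img[6, 4], tolerance = 1e-4)
  } else {
    fail(paste("independent MRC reader unavailable:",
               paste(out, collapse = " ")))
  }
  unlink(f)
})

test_that("unsupported or truncated MRC files raise clear errors", {
  f <- tempfile(fileext = ".mrc")
  img <- matrix(0, 32, 32)
  write_mrc(img, f)
  # corrupt the mode word
  con <- file(f, "r+b")
  seek(con, 12, rw = "write")
  writeBin(6L, con, size = 4, endian = "little")
  close(con)
  expect_error(read_micrograph(f), "mode")
  write_mrc(matrix(rnorm(64 * 64), 64), f)
  truncated <- readBin(f, "raw", n = 2048)
  writeBin(truncated, f)
  expect_error(read_micrograph(f), "truncated")
  unlink(f)
  expect_error(read_micrograph(tempfile()), "no such file")
})

test_that("TIFF, PNG and JPG inputs collapse to one gray channel", {
  f <- tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(0, 32, 32), f)
  z <- read_micrograph(f)
  expect_equal(dim(z), c(32, 32))
  expect_true(all(z == 0))
  unlink(f)
  # RGB png averages channels
  f2 <- tempfile(fileext = ".png")
  arr <- array(runif(32 * 32 * 3), c(32, 32, 3))
  png::writePNG(arr, f2)
  g <- read_micrograph(f2)
  expect_equal(unclass(g)[, ], apply(png::readPNG(f2), c(1, 2), mean),
               tolerance = 1e-6, ignore_attr = TRUE)
  unlink(f2)
  # JPG is lossy; demand agreement only to compression error
  f3 <- tempfile(fileext = ".jpg")
  smooth <- outer(seq(0, 1, length.out = 64), seq(0, 1, length.out = 64),
                  function(a, b) (a + b) / 2)
  jpeg::writeJPEG(smooth, f3, quality = 0.95)
  j <- read_micrograph(f3)
  expect_equal(dim(j), c(64, 64))
  expect_lt(mean(abs(j - smooth)), 0.02)
  unlink(f3)
})

test_that("EMAN1 box corners convert to centers and back", {
  f <- tempfile(fileext = ".box")
  writeLines("80\t80\t40\t40", f)
  b <- read_boxes(f)
  expect_equal(b$cx, 100)
  expect_equal(b$cy, 100)
  expect_equal(b$w, 40)
  write_boxes(b, f, format = "eman1_box")
  expect_equal(strsplit(readLines(f), "\\s+")[[1]], c("80", "80", "40",
                                                      "40"))
  # empty file
  writeLines(character(), f)
  expect_equal(nrow(read_boxes(f)), 0)
  # malformed line reports its number
  writeLines(c("10 10 20 20", "not a box"), f)
  expect_error(read_boxes(f), "line 2")
  unlink(f)
})

test_that("STAR coordinates are centers with configured box size", {
  f <- tempfile(fileext = ".star")
  writeLines(c("", "data_", "", "loop_", "_rlnCoordinateX #1",
               "_rlnCoordinateY #2", "100.0 100.0", "17.5 42.0"), f)
  b <- read_boxes(f, box_size = 40)
  expect_equal(b$cx, c(100, 17.5))
  expect_equal(b$w, c(40, 40))
  expect_error(read_boxes(f), "box_size")
  # missing coordinate columns
  writeLines(c("data_", "loop_", "_rlnSomething #1", "1.0"), f)
  expect_error(read_boxes(f, format = "star", box_size = 40),
               "_rlnCoordinate")
  unlink(f)
})

test_that("STAR output declares the expected header and round-trips", {
  b <- boxes_df(cx = c(10.25, 200), cy = c(30.5, 40), w = 36, h = 36,
                confidence = c(0.75, 0.5))
  f <- tempfile(fileext = ".star")
  write_boxes(b, f, format = "star")
  txt <- readLines(f)
  expect_true(any(grepl("_rlnCoordinateX", txt)))
  expect_true(any(grepl("_rlnCoordinateY", txt)))
  b2 <- read_boxes(f, box_size = 36)
  expect_equal(b2$cx, b$cx, tolerance = 1e-5)
  expect_equal(b2$cy, b$cy, tolerance = 1e-5)
  expect_equal(b2$confidence, b$confidence, tolerance = 1e-5)
  unlink(f)
})

test_that("random boxes survive write/read in both formats within 0.5 px", {
  set.seed(24)
  b <- random_boxes(100, lim = 900, wmin = 20, wmax = 21)
  b$w <- round(b$w); b$h <- round(b$h)
  class(b) <- c("boxes", "data.frame")
  f <- tempfile()
  write_boxes(b, f, format = "eman1_box")
  b2 <- read_boxes(f, format = "eman1_box")
  expect_lt(max(abs(b2$cx - b$cx)), 0.5 + 1e-9)
  expect_lt(max(abs(b2$cy - b$cy)), 0.5 + 1e-9)
  write_boxes(b, f, format = "star")
  b3 <- read_boxes(f, format = "star", box_size = b$w[1])
  expect_lt(max(abs(b3$cx - b$cx)), 1e-5)
  # y-flip is its own inverse through a write/read cycle
  write_boxes(b, f, format = "eman1_box", flip_y = TRUE,
              image_height = 1000)
  b4 <- read_boxes(f, format = "eman1_box", flip_y = TRUE,
                   image_height = 1000)
  expect_lt(max(abs(b4$cy - b$cy)), 0.5 + 1e-9)
  unlink(f)
})

test_that("micrograph constructor enforces its invariants", {
  expect_error(micrograph(matrix(0, 10, 10)), "32")
  m <- matrix(0, 32, 32); m[1] <- NA
  expect_error(micrograph(m), "finite")
})
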