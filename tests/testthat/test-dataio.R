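test_that("modality normalization maps the printed ranges", {
  # x-ray: [0, 255] -> [-1, 1]
  xr <- matrix(c(0, 127.5, 255, 64), 2)
  n <- normalize_image(xr, "xray")
  expect_equal(n[1, 1], -1)
  expect_equal(n[2, 1], 0)
  expect_equal(n[1, 2], 1)
  # CT: [-1024, 3012] -> [0, 1]
  ct <- normalize_image(matrix(c(-1024, 3012), 1), "ct")
  expect_equal(as.vector(ct), c(0, 1))
  # MRI: per-scan min/max -> [-1, 1]
  mr <- matrix(c(10, 30, 50, 20), 2)
  nm <- normalize_image(mr, "mri")
  expect_equal(range(nm), c(-1, 1))
  expect_error(normalize_image(matrix(5, 2, 2), "mri"), "zero dynamic range")
  expect_error(normalize_image(mr, "pet"), "unknown modality")
})

test_that("denormalization clips then inverts the affine map", {
  expect_equal(denormalize_image(matrix(1.2), "ct"), matrix(3012))
  expect_equal(denormalize_image(matrix(c(-1, 1), 1), "xray"),
               matrix(c(0, 255), 1))
  set.seed(50)
  x <- matrix(runif(16, 0, 255), 4)
  rt <- denormalize_image(normalize_image(x, "xray"), "xray")
  expect_equal(rt, x, tolerance = 1e-6)
  mr <- matrix(runif(16, 120, 900), 4)
  nm <- normalize_image(mr, "mri")
  expect_equal(denormalize_image(nm, "mri", attr(nm, "raw_range")), mr,
               tolerance = 1e-6)
})

test_that("geometry conforming pads centered with edge replication", {
  set.seed(51)
  img <- matrix(runif(200 * 256), 200, 256)
  out <- conform_geometry(img, 256, "pad")
  expect_equal(dim(out), c(256, 256))
  expect_equal(out[29:228, ], img)
  for (i in 1:28) expect_equal(out[i, ], img[1, ])       # replicated top rows
  for (i in 229:256) expect_equal(out[i, ], img[200, ])  # replicated bottom
  same <- matrix(runif(64), 8)
  expect_identical(conform_geometry(same, 8, "pad"), same)
  expect_error(conform_geometry(img, 128, "pad"), "target_side")
  rs <- conform_geometry(img, 64, "resample")
  expect_equal(dim(rs), c(64, 64))
  # resampling a constant image is exact
  expect_equal(conform_geometry(matrix(0.4, 10, 10), 16, "resample"),
               matrix(0.4, 16, 16))
})

test_that("PNG codec round-trips 8-bit grayscale", {
  set.seed(52)
  m <- matrix(sample(0:255, 40 * 28, replace = TRUE), 40, 28)
  path <- withr::local_tempfile(fileext = ".png")
  write_png_gray(m, path)
  expect_identical(read_png_gray(path), m)
  expect_error(write_png_gray(matrix(300, 2, 2), path), "0..255")
  # reader rejects non-PNG input
  bad <- withr::local_tempfile()
  writeBin(as.raw(1:32), bad)
  expect_error(read_png_gray(bad), "not a PNG")
})

test_that("PNG reader undoes all five scanline filters", {
  # hand-build a filtered PNG: same pixels, each row filtered differently
  set.seed(53)
  ns <- asNamespace("swindiff")
  m <- matrix(sample(0:255, 5 * 7, replace = TRUE), 5, 7)
  filt <- list()
  prev <- integer(7)
  types <- c(0L, 1L, 2L, 3L, 4L)
  for (i in 1:5) {
    cur <- m[i, ]
    ft <- types[i]
    enc <- integer(7)
    for (j in 1:7) {
      left <- if (j > 1) cur[j - 1] else 0L
      up <- prev[j]
      ul <- if (j > 1) prev[j - 1] else 0L
      pred <- switch(as.character(ft), "0" = 0L, "1" = left, "2" = up,
                     "3" = as.integer(floor((left + up) / 2)),
                     "4" = {p <- left + up - ul
                            pa <- abs(p - left); pb <- abs(p - up); pc <- abs(p - ul)
                            if (pa <= pb && pa <= pc) left
                            else if (pb <= pc) up else ul})
      enc[j] <- (cur[j] - pred) %% 256L
    }
    filt[[i]] <- c(ft, enc)
    prev <- cur
  }
  raw_data <- as.raw(unlist(filt))
  ihdr <- c(ns$u32_bytes(7), ns$u32_bytes(5), as.raw(c(8, 0, 0, 0, 0)))
  bytes <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
             ns$png_chunk("IHDR", ihdr),
             ns$png_chunk("IDAT", memCompress(raw_data, "gzip")),
             ns$png_chunk("IEND", raw()))
  path <- withr::local_tempfile(fileext = ".png")
  writeBin(bytes, path)
  expect_identical(read_png_gray(path), m)
})

test_that("NIfTI codec round-trips float32 slices with spacing", {
  set.seed(54)
  m <- matrix(runif(12 * 9, -500, 2000), 12, 9)
  for (ext in c(".nii", ".nii.gz")) {
    path <- withr::local_tempfile(fileext = ext)
    write_nifti_2d(m, path, pixel_spacing = c(2, 1.5))
    r <- read_nifti_2d(path)
    expect_equal(unclass(r), m, tolerance = 1e-4, ignore_attr = TRUE)
    expect_equal(attr(r, "pixel_spacing"), c(2, 1.5), tolerance = 1e-6)
  }
})

test_that("image sets validate their invariants and round-trip to disk", {
  set.seed(55)
  imgs <- lapply(1:4, function(i) matrix(runif(64, -1, 1), 8))
  expect_error(image_set(list(), "phantom"), "empty")
  expect_error(image_set(c(imgs, list(matrix(0, 4, 4))), "phantom"),
               "one resolution")
  expect_error(image_set(list(matrix(2, 8, 8)), "phantom"), "outside")
  s <- image_set(imgs, "phantom")
  d1 <- withr::local_tempdir()
  save_image_set(s, d1, "png")
  r1 <- load_image_set(d1)
  expect_equal(length(r1$images), 4)
  # PNG is 8-bit quantized: half-bin accuracy on the [-1, 1] scale
  for (i in 1:4)
    expect_lt(max(abs(r1$images[[i]] - s$images[[i]])), 1 / 255)
  ctimgs <- lapply(1:3, function(i) matrix(runif(64, 0, 1), 8))
  sc <- image_set(ctimgs, "ct", pixel_spacing = c(2, 2))
  d2 <- withr::local_tempdir()
  save_image_set(sc, d2, "nifti")
  r2 <- load_image_set(d2)
  for (i in 1:3)
    expect_equal(r2$images[[i]], ctimgs[[i]], tolerance = 1e-6)
  expect_equal(r2$pixel_spacing, c(2, 2))
  expect_error(load_image_set(withr::local_tempdir()), "manifest")
})
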