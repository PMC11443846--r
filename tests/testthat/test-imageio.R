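test_that("grayscale and RGB images load as 8-bit rasters", {
  d <- withr::local_tempdir()

  # black RGB image
  f <- file.path(d, "black.png")
  png::writePNG(array(0, c(2, 2, 3)), f)
  img <- load_gray_image(f)
  expect_identical(as.integer(img), rep(0L, 4))
  expect_identical(attr(img, "source_name"), "black.png")

  # 16-bit full-scale TIFF maps its maximum representable value to 255
  f <- file.path(d, "full.tif")
  tiff::writeTIFF(matrix(1, 2, 2), f, bits.per.sample = 16L)
  expect_identical(as.integer(load_gray_image(f)), rep(255L, 4))

  # BT.601 luminance of pure R, G, B, rounded
  f <- file.path(d, "rgb.png")
  arr <- array(0, c(1, 3, 3))
  arr[1, 1, 1] <- 1; arr[1, 2, 2] <- 1; arr[1, 3, 3] <- 1
  png::writePNG(arr, f)
  expect_identical(as.integer(load_gray_image(f)), c(76L, 150L, 29L))

  # same raster through JPEG survives at JPEG quality 1 on flat fields
  f <- file.path(d, "flat.jpg")
  jpeg::writeJPEG(matrix(0.5, 16, 16), f, quality = 1)
  img <- load_gray_image(f)
  expect_equal(dim(img), c(16L, 16L))
  expect_true(all(img >= 0 & img <= 255))
})

test_that("unsupported and unreadable files raise decode errors", {
  d <- withr::local_tempdir()
  f <- file.path(d, "notes.txt")
  writeLines("not an image", f)
  expect_error(load_gray_image(f), class = "fociquant_decode_error")
  garbage <- file.path(d, "bad.png")
  writeBin(as.raw(1:32), garbage)
  expect_error(load_gray_image(garbage), class = "fociquant_decode_error")
  expect_error(load_gray_image(file.path(d, "missing.png")),
               class = "fociquant_decode_error")
})

test_that("8-bit grayscale PNG round trip is lossless", {
  d <- withr::local_tempdir()
  set.seed(11)
  img <- random_image(13, 17)
  f <- file.path(d, "x.png")
  png::writePNG(img / 255, f)
  expect_identical(unclass(load_gray_image(f))[, ], img)
})

test_that("batches pair by sorted filename rank and validate counts/shapes", {
  d <- withr::local_tempdir()
  mdir <- file.path(d, "marker"); ddir <- file.path(d, "damage")
  dir.create(mdir); dir.create(ddir)
  set.seed(2)
  for (nm in c("b.png", "a.png")) {
    png::writePNG(random_image(8, 8) / 255, file.path(mdir, nm))
    png::writePNG(random_image(8, 8) / 255, file.path(ddir, nm))
  }
  batch <- discover_batch(mdir, ddir)
  expect_s3_class(batch, "channel_batch")
  expect_identical(batch$marker_name, c("a.png", "b.png"))
  expect_identical(batch$damage_name, c("a.png", "b.png"))

  # unequal counts
  png::writePNG(random_image(8, 8) / 255, file.path(mdir, "c.png"))
  expect_error(discover_batch(mdir, ddir), class = "fociquant_batch_mismatch")
  file.remove(file.path(mdir, "c.png"))

  # shape mismatch names both files
  png::writePNG(random_image(8, 9) / 255, file.path(ddir, "a.png"))
  err <- expect_error(discover_batch(mdir, ddir),
                      class = "fociquant_shape_mismatch")
  expect_match(conditionMessage(err), "a.png")

  # empty folder
  edir <- file.path(d, "empty"); dir.create(edir)
  expect_error(discover_batch(edir, ddir), class = "fociquant_empty_batch")

  # mismatched basenames pair by rank with a warning
  file.remove(file.path(ddir, "a.png"), file.path(ddir, "b.png"))
  png::writePNG(random_image(8, 8) / 255, file.path(ddir, "x1.png"))
  png::writePNG(random_image(8, 8) / 255, file.path(ddir, "x2.png"))
  expect_warning(b2 <- discover_batch(mdir, ddir), "paired by sorted rank")
  expect_identical(b2$damage_name, c("x1.png", "x2.png"))
})

test_that("label images use one distinct palette color per label", {
  d <- withr::local_tempdir()
  lab <- matrix(0L, 10, 10)
  f <- file.path(d, "lab.png")

  write_label_image(lab, f)
  expect_identical(distinct_png_colors(f), 1L)  # all black

  lab[2:3, 2:3] <- 1L
  lab[7:8, 7:9] <- 2L
  write_label_image(lab, f)
  expect_identical(distinct_png_colors(f), 3L)  # black + 2 labels

  # reloaded color count tracks the labels present for many label counts
  set.seed(3)
  lab <- matrix(sample(0:9, 400, replace = TRUE), 20, 20)
  write_label_image(lab, f)
  expect_identical(distinct_png_colors(f), length(unique(as.integer(lab))))
})

test_that("overlays recolor exactly the labeled focus pixels", {
  d <- withr::local_tempdir()
  set.seed(4)
  raw <- random_image(12, 12)
  lab <- matrix(0L, 12, 12)
  f <- file.path(d, "ov.png")

  write_overlay(raw, lab, f)
  arr <- png::readPNG(f)
  gray <- arr[, , 1] == arr[, , 2] & arr[, , 2] == arr[, , 3]
  expect_true(all(gray))
  expect_equal(round(arr[, , 1] * 255), raw, ignore_attr = TRUE)

  lab[5:6, 5:6] <- 1L
  write_overlay(raw, lab, f)
  arr <- png::readPNG(f)
  gray <- arr[, , 1] == arr[, , 2] & arr[, , 2] == arr[, , 3]
  expect_identical(sum(!gray), 4L)

  expect_error(write_overlay(raw, matrix(0L, 3, 3), f),
               class = "fociquant_invalid_input")
})
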