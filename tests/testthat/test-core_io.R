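test_that("image2d enforces its invariants", {
  m <- matrix(0:3, 2, 2)
  img <- image2d(m, 0.5)
  expect_s3_class(img, "image2d")
  expect_identical(dim(img), c(2L, 2L))
  expect_error(image2d(m, 0), "pixel_size_um")
  expect_error(image2d(m, -1), "pixel_size_um")
  expect_error(image2d(matrix(-1, 2, 2), 0.5), "non-negative")
  expect_error(image2d(matrix(300, 2, 2), 0.5, bit_depth = 8), "bit depth")
  expect_silent(image2d(matrix(300, 2, 2), 0.5, bit_depth = 16))
})

test_that("grayscale conversion is luminance-weighted and idempotent", {
  rgb <- array(0, dim = c(4, 4, 3))
  rgb[, , 1] <- 100; rgb[, , 2] <- 100; rgb[, , 3] <- 100
  # identical channels: grayscale equals any channel
  expect_equal(rgb_to_gray(rgb), matrix(100, 4, 4))
  g <- rgb_to_gray(rgb)
  expect_identical(rgb_to_gray(g), g) # idempotent on single channel
  rgb[, , 1] <- 255; rgb[, , 2] <- 0; rgb[, , 3] <- 0
  expect_equal(rgb_to_gray(rgb)[1, 1], round(0.299 * 255))
})

test_that("TIFF images round-trip bit-exactly (8- and 16-bit)", {
  withr::with_tempdir({
    set.seed(1)
    m8 <- matrix(sample(0:255, 64 * 48, replace = TRUE), 48, 64)
    img <- image2d(m8, 0.5, hemisphere = "left", channel = "DAPI")
    write_image(img, "a.tif")
    back <- read_image("a.tif", 0.5, hemisphere = "left", channel = "DAPI")
    expect_identical(back$pixels, m8)
    expect_identical(back$bit_depth, 8L)
    m16 <- matrix(sample(0:65535, 32 * 32, replace = TRUE), 32, 32)
    write_image(image2d(m16, 1, bit_depth = 16), "b.tif")
    back16 <- read_image("b.tif", 1)
    expect_identical(back16$pixels, m16)
    expect_identical(back16$bit_depth, 16L)
  })
})

test_that("PNG images round-trip bit-exactly (8-bit)", {
  withr::with_tempdir({
    set.seed(2)
    m <- matrix(sample(0:255, 40 * 40, replace = TRUE), 40, 40)
    write_image(image2d(m, 0.25), "a.png")
    back <- read_image("a.png", 0.25)
    expect_equal(back$pixels, m)
  })
})

test_that("read_image rejects bad inputs", {
  expect_error(read_image("no-such-file.png", 1), "not found")
  withr::with_tempdir({
    writeLines("x", "f.xyz")
    expect_error(read_image("f.xyz", 1), "unsupported")
    write_image(image2d(matrix(1, 2, 2), 1), "ok.png")
    expect_error(read_image("ok.png", 0), "pixel_size_um")
  })
})

test_that("cilia CSV round-trips records", {
  withr::with_tempdir({
    write_cilia_csv(data.frame(), "empty.csv")
    expect_identical(length(readLines("empty.csv")), 1L) # header only
    rec <- data.frame(
      id = 1:3, section_id = "s1", region_label = "CA1",
      hemisphere = c("left", "right", "left"), zt = c(0, 2, 4),
      length_um = c(5.123456, 2.5, 14.999999),
      width_um = c(1.1, 0.9, 2), angle_deg = c(0, 123.456789, 359.9),
      base_x = c(1, 2, 3), base_y = c(4, 5, 6),
      centroid_x = c(1.5, 2.5, 3.5), centroid_y = c(4.5, 5.5, 6.5),
      stringsAsFactors = FALSE
    )
    write_cilia_csv(rec, "rec.csv")
    expect_identical(length(readLines("rec.csv")), 4L) # header + 3
    back <- read_cilia_csv("rec.csv")
    num <- vapply(rec, is.numeric, logical(1))
    for (col in names(rec)[num]) {
      expect_equal(back[[col]], rec[[col]], tolerance = 1e-6, label = col)
    }
    expect_identical(back$hemisphere, rec$hemisphere)
  })
})

test_that("config files parse keys, numbers and booleans", {
  withr::with_tempdir({
    writeLines(c("pixel_size_um = 0.5 # microns per pixel",
                 "min_aspect=1.5", "drop_border = true", "label = CA1"),
               "cfg.txt")
    cfg <- read_config("cfg.txt")
    expect_identical(cfg$pixel_size_um, 0.5)
    expect_identical(cfg$min_aspect, 1.5)
    expect_true(cfg$drop_border)
    expect_identical(cfg$label, "CA1")
    expect_error(read_config("missing.txt"), "not found")
  })
})
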