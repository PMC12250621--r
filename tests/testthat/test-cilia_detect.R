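test_that("extract_cilia_contours uses median-scaled Canny thresholds", {
  img <- bar_image(fg = 200, bg = 90) # median intensity 90
  pre <- preprocess(img)
  med <- median(pre$pixels)
  expect_equal(med, 90)
  manual <- canny_edges(pre$pixels, 0.67 * 90, 1.33 * 90) # lower = 60.3
  auto <- attr(extract_cilia_contours(pre), "binary")
  expect_identical(auto, binary_erode(binary_close(manual, c(2, 2)), c(1, 1)))
  expect_length(extract_cilia_contours(preprocess(
    image2d(matrix(0, 32, 32), 0.5))), 0L)
})

test_that("an isolated bright bar yields exactly one contour", {
  img <- bar_image()
  cts <- extract_cilia_contours(preprocess(img))
  expect_length(cts, 1L)
})

test_that("contour filtering enforces the length and aspect bounds", {
  img <- image2d(matrix(0, 100, 100), 0.1) # 0.1 um/px
  make <- function(len_um, aspect) rect_contour(len_um / 0.1, len_um / 0.1 / aspect)
  cts <- list(
    make(0.5, 3),  # too short
    make(10, 4),   # keep
    make(10, 1.2), # not elongated enough
    make(9, 1.5),  # keep: aspect boundary is inclusive (90/60 px is exact)
    make(16, 3)    # too long
  )
  kept <- filter_cilia_contours(cts, img)
  expect_identical(kept, cts[c(2, 4)])
})

test_that("measure_cilium returns physical dimensions and math-convention angle", {
  ct <- rect_contour(20, 4)
  m <- measure_cilium(ct, 0.5)
  expect_equal(m$length_um, 10)
  expect_equal(m$width_um, 2)
  expect_equal(m$raw_angle_deg, 0)
  # rotated 45 deg (y-up): length preserved, angle recovered
  rad <- -45 * pi / 180 # image-coords rotation for +45 math
  R <- matrix(c(cos(rad), sin(rad), -sin(rad), cos(rad)), 2, 2)
  pts <- sweep(rect_contour(20, 4, 0, 0), 2, c(0, 0)) %*% t(R)
  m45 <- measure_cilium(cbind(x = pts[, 1], y = pts[, 2]), 0.5)
  o <- oracle_min_rect(cbind(pts[, 1], -pts[, 2]))
  expect_equal(m45$length_um, 0.5 * o$length, tolerance = 0.02 * o$length)
  expect_equal(m45$raw_angle_deg, 45, tolerance = 1)
  # square blob: aspect ratio 1
  sq <- measure_cilium(rect_contour(6, 6), 1)
  expect_equal(sq$length_um / sq$width_um, 1)
})

test_that("locate_base finds the brightest pixel inside the mask", {
  img <- bar_image(r0 = 30, r1 = 33, c0 = 15, c1 = 45, fg = 100)
  img$pixels[31, 16] <- 255 # bright base at the left end
  ct <- extract_contours(matrix(as.integer(img$pixels > 50), 64))[[1]]
  b <- locate_base(ct, img)
  expect_equal(unname(b), c(16, 31))
  # uniform bar: first maximal pixel in raster order (smallest row, then col)
  img2 <- bar_image(fg = 100)
  ct2 <- extract_contours(matrix(as.integer(img2$pixels > 50), 64))[[1]]
  b2 <- locate_base(ct2, img2)
  expect_equal(unname(b2), c(15, 30))
  # result always lies inside the contour mask
  expect_true(img$pixels[b[["y"]], b[["x"]]] >= 100)
})

test_that("finalize_angle orients base-to-tip and mirrors the left hemisphere", {
  # horizontal bar, base left, centroid right -> 0 (right hemisphere)
  expect_equal(finalize_angle(0, c(10, 50), c(20, 50), "right"), 0)
  # base right -> 180
  expect_equal(finalize_angle(0, c(30, 50), c(20, 50), "right"), 180)
  # atan2 oracle: base (0,0), centroid at math direction (3,4)
  raw <- (atan2(4, 3) * 180 / pi) %% 180
  expect_equal(finalize_angle(raw, c(0, 0), c(3, -4), "right"),
               atan2(4, 3) * 180 / pi, tolerance = 1e-9) # 53.13
  expect_equal(finalize_angle(raw, c(0, 0), c(3, -4), "left"),
               180 - atan2(4, 3) * 180 / pi, tolerance = 1e-9) # 126.87
  expect_warning(ang <- finalize_angle(10, c(5, 5), c(5, 5), "right"),
                 "undefined")
  expect_true(is.na(ang))
})

test_that("detect_cilia composes the pipeline and respects the filters", {
  expect_identical(nrow(detect_cilia(image2d(matrix(0, 64, 64), 0.5))), 0L)
  sc <- synth_cilia_image(n = 5, shape = c(512L, 512L), seed = 11)
  det <- detect_cilia(sc$image)
  m <- match_detections(det, sc$truth, 5)
  expect_identical(nrow(m), 5L) # all five recovered
  expect_true(all(det$length_um > 1 & det$length_um < 15))
  expect_true(all(det$length_um / det$width_um >= 1.5 | det$width_um == 0))
  expect_true(all(det$angle_deg >= 0 & det$angle_deg < 360))
})

test_that("detection is deterministic", {
  sc <- synth_cilia_image(n = 4, shape = c(384L, 384L), seed = 12)
  expect_identical(detect_cilia(sc$image), detect_cilia(sc$image))
})

test_that("left-hemisphere angles mirror right-hemisphere angles", {
  sc <- synth_cilia_image(n = 4, shape = c(384L, 384L), seed = 13)
  det_r <- detect_cilia(sc$image)
  img_l <- sc$image; img_l$hemisphere <- "left"
  det_l <- detect_cilia(img_l)
  expect_identical(nrow(det_r), nrow(det_l))
  expect_equal((180 - det_r$angle_deg) %% 360, det_l$angle_deg)
})
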