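test_that("gaussian blur preserves constants, shape and matches direct convolution", {
  const <- matrix(7, 16, 16)
  expect_equal(gaussian_blur_matrix(const), const)
  set.seed(3)
  m <- matrix(runif(20 * 24, 0, 255), 20, 24)
  out <- gaussian_blur_matrix(m, round = FALSE)
  expect_identical(dim(out), dim(m))
  # impulse response equals the brute-force convolution oracle
  imp <- matrix(0, 11, 11); imp[6, 6] <- 100
  k <- ciliomorph:::gaussian_kernel_1d(3)
  k2 <- outer(k, k)
  expect_equal(gaussian_blur_matrix(imp, round = FALSE),
               oracle_conv2(imp, k2), tolerance = 1e-12)
  expect_equal(gaussian_blur_matrix(m, round = FALSE),
               oracle_conv2(m, k2), tolerance = 1e-9)
})

test_that("canny finds an isolated bar as a single closed component", {
  img <- bar_image()
  e <- canny_edges(img$pixels, 20, 40)
  expect_gt(sum(e), 0)
  closed <- binary_close(e, c(2, 2))
  expect_identical(attr(label_components(closed), "n"), oracle_cc_count(closed))
  expect_identical(oracle_cc_count(closed), 1L)
  # blank image: no edges at all
  expect_identical(sum(canny_edges(matrix(0, 32, 32), 10, 20)), 0L)
})

test_that("morphology: 1x1 kernels are the identity, 2x2 close bridges 1-px gaps", {
  m <- matrix(0L, 10, 10); m[3:7, 4] <- 1L; m[5, 8] <- 1L
  expect_identical(binary_erode(m, c(1, 1)), m)
  expect_identical(binary_dilate(m, c(1, 1)), m)
  gap <- matrix(0L, 8, 8); gap[4, 2:3] <- 1L; gap[4, 5:6] <- 1L
  expect_identical(oracle_cc_count(binary_close(gap, c(2, 2))), 1L)
})

test_that("adaptive mean threshold segments against the local mean", {
  m <- matrix(50, 30, 30)
  m[15, 15] <- 100
  bin <- adaptive_threshold_mean(m, 5, -10)
  expect_identical(bin[15, 15], 1L)   # 100 > mean+10
  expect_identical(sum(bin), 1L)      # flat background stays off
  # C = -10 means threshold is local mean + 10
  m2 <- matrix(50, 10, 10); m2[5, 5] <- 59
  expect_identical(sum(adaptive_threshold_mean(m2, 9, -10)), 0L)
})

test_that("distance transform matches the brute-force oracle", {
  set.seed(4)
  for (i in 1:5) {
    mask <- matrix(rbinom(15 * 15, 1, 0.6), 15, 15)
    expect_equal(distance_transform(mask), oracle_distance_transform(mask),
                 tolerance = 1e-9)
  }
  d <- distance_transform(disk_mask(31, 31, 16, 16, 10))
  expect_identical(which.max(d), which(disk_mask(31, 31, 16, 16, 0.5) == 1))
})

test_that("contour extraction returns one external boundary per component", {
  m <- matrix(0L, 20, 20)
  m[3:6, 3:6] <- 1L
  m[12:17, 10:16] <- 1L
  m[14, 12:14] <- 0L # interior hole: still one external contour
  cts <- extract_contours(m)
  expect_length(cts, 2L)
  # all contour points are boundary pixels of the mask
  for (ct in cts) expect_true(all(m[cbind(ct[, 2], ct[, 1])] == 1L))
  expect_length(extract_contours(matrix(0L, 5, 5)), 0L)
})

test_that("hole filling closes enclosed background only", {
  m <- matrix(0L, 12, 12)
  m[3:9, 3:9] <- 1L; m[5:7, 5:7] <- 0L
  f <- ciliomorph:::fill_holes(m)
  expect_identical(sum(f), 49L)      # 7x7 solid block
  expect_identical(f[1, 1], 0L)      # outside untouched
})

test_that("CLAHE output is a valid 8-bit image and is deterministic", {
  set.seed(5)
  m <- matrix(sample(0:255, 64 * 64, replace = TRUE), 64, 64)
  out <- clahe(m, 2.0, c(4, 4))
  expect_identical(dim(out), dim(m))
  expect_true(all(out >= 0 & out <= 255))
  expect_identical(out, clahe(m, 2.0, c(4, 4)))
  # contrast of a low-contrast gradient increases
  g <- matrix(rep(seq(100, 120, length.out = 64), each = 64), 64, 64)
  expect_gt(diff(range(clahe(g, 4, c(2, 2)))), diff(range(g)))
})
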