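test_that("cilia scenes honour their contracts and are seed-deterministic", {
  empty <- synth_cilia_image(n = 0, shape = c(128L, 128L), seed = 1)
  expect_identical(nrow(empty$truth), 0L)
  expect_identical(dim(empty$image$pixels), c(128L, 128L))
  sc <- synth_cilia_image(n = 5, shape = c(512L, 512L), seed = 2)
  expect_identical(nrow(sc$truth), 5L)
  expect_true(all(sc$truth$length_um > 2 & sc$truth$length_um < 12))
  # rendered angle equals atan2 of (tip - base) in the math convention
  ang <- (atan2(-(sc$truth$tip_y - sc$truth$base_y),
                sc$truth$tip_x - sc$truth$base_x) * 180 / pi) %% 360
  expect_equal(ang, sc$truth$angle_deg, tolerance = 1e-9)
  # length consistent with base/tip geometry
  len <- sqrt((sc$truth$tip_x - sc$truth$base_x)^2 +
              (sc$truth$tip_y - sc$truth$base_y)^2) * 0.5
  expect_equal(len, sc$truth$length_um, tolerance = 1e-9)
  # pairwise separation respected
  for (i in 1:4) for (j in (i + 1):5) {
    d <- ciliomorph:::segment_segment_distance(
      c(sc$truth$base_x[i], sc$truth$base_y[i]),
      c(sc$truth$tip_x[i], sc$truth$tip_y[i]),
      c(sc$truth$base_x[j], sc$truth$base_y[j]),
      c(sc$truth$tip_x[j], sc$truth$tip_y[j]))
    expect_gte(d, 20)
  }
  again <- synth_cilia_image(n = 5, shape = c(512L, 512L), seed = 2)
  expect_identical(sc$image$pixels, again$image$pixels) # bit-identical
  expect_identical(sc$truth, again$truth)
})

test_that("nuclei scenes place disks of the requested geometry", {
  sc <- synth_nuclei_image(n = 20, shape = c(768L, 768L), seed = 3)
  expect_identical(nrow(sc$truth), 20L)
  expect_true(all(sc$truth$radius_px >= 4 & sc$truth$radius_px <= 10))
  # disk pixel area tracks pi r^2 (count bright pixels near one isolated disk)
  one <- synth_nuclei_image(n = 1, shape = c(128L, 128L),
                            radius_range_px = c(8, 8), bg_sd = 0, seed = 4)
  area <- sum(one$image$pixels > 40)
  expect_equal(area, pi * 64, tolerance = 0.15 * pi * 64)
  again <- synth_nuclei_image(n = 20, shape = c(768L, 768L), seed = 3)
  expect_identical(sc$image$pixels, again$image$pixels)
})

test_that("time series follow the cosine model exactly at zero noise", {
  rp <- data.frame(region_label = c("A", "B"), mesor = c(5, 6),
                   amplitude = c(1, 0), phase = c(6, 0), noise_sd = 0)
  ts <- synth_timeseries(rp, sections_per_zt = 3, seed = 5)
  a <- ts[ts$region_label == "A", ]
  expect_equal(a$value, 5 + cos(2 * pi * (a$zt - 6) / 24), tolerance = 1e-12)
  b <- ts[ts$region_label == "B", ]
  expect_true(all(b$value == 6))          # amplitude 0: flat series
  # cosinor on per-ZT means recovers the planted phase exactly
  f <- cosinor_fit(a$zt, a$value)
  expect_equal(f$phase, 6, tolerance = 1e-8)
  expect_equal(f$amplitude, 1, tolerance = 1e-8)
  # noisy series keeps the sampling design
  ts2 <- synth_timeseries(transform(rp, noise_sd = 0.3), seed = 6)
  expect_identical(nrow(ts2), 2L * 12L * 12L)
})

test_that("planted-partition matrices are block-structured and recoverable", {
  comm <- setNames(rep(c(1, 2, 3), each = 5), paste0("R", 1:15))
  net0 <- synth_connectivity(comm, w_in = 1, w_out = 0, seed = 7)
  off_block <- net0$W[comm[row(net0$W)] != comm[col(net0$W)]]
  expect_true(all(off_block == 0))        # w_out = 0: block diagonal
  net <- synth_connectivity(comm, w_in = 1, w_out = 0.05, seed = 8)
  rec <- detect_communities(net$W, seed = 1)
  # exact recovery up to label permutation
  expect_identical(length(unique(rec)), 3L)
  expect_true(all(tapply(rec, comm, function(x) length(unique(x))) == 1))
  again <- synth_connectivity(comm, w_in = 1, w_out = 0.05, seed = 8)
  expect_identical(net$W, again$W)
})
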