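test_that("one-way ANOVA matches hand-computed sums of squares", {
  # constant data: F = 0, p = 1
  a0 <- anova_time_effect(rep(3, 6), rep(c(0, 2, 4), each = 2))
  expect_equal(a0$F, 0); expect_equal(a0$p, 1)
  # 3-group toy {1,2},{1,2},{10,11}
  v <- c(1, 2, 1, 2, 10, 11)
  g <- rep(c(0, 2, 4), each = 2)
  a <- anova_time_effect(v, g)
  gm <- mean(v)
  ssb <- sum(2 * (tapply(v, g, mean) - gm)^2)
  ssw <- sum((v - rep(tapply(v, g, mean), each = 2))^2)
  Fexp <- (ssb / 2) / (ssw / 3)
  expect_equal(a$F, Fexp, tolerance = 1e-12)
  expect_equal(a$p, pf(Fexp, 2, 3, lower.tail = FALSE), tolerance = 1e-12)
  # shift invariance
  a_shift <- anova_time_effect(v + 100, g)
  expect_equal(a_shift$p, a$p, tolerance = 1e-12)
  expect_error(anova_time_effect(1:3, rep(0, 3)), "2 ZT groups")
})

test_that("two-stage BKY FDR handles the edge cases", {
  expect_identical(sum(fdr_bky(rep(1, 10))$reject), 0L)
  expect_true(fdr_bky(1e-9)$reject)
  expect_identical(fdr_bky(numeric(0))$reject, logical(0))
  expect_error(fdr_bky(c(0.5, 1.2)), "0, 1")
  r <- fdr_bky(c(0.001, 0.008, 0.039, 0.041, 0.9), 0.05)
  expect_identical(r$reject, oracle_bky(c(0.001, 0.008, 0.039, 0.041, 0.9)))
})

test_that("BKY matches the enumeration oracle on random p-vectors", {
  set.seed(41)
  for (i in 1:60) {
    m <- sample(3:40, 1)
    # mixture of nulls and signals exercises both stages
    p <- c(runif(m), rbeta(sample(0:5, 1), 0.2, 8))
    r <- fdr_bky(p)
    expect_identical(r$reject, oracle_bky(p))
    # rejections monotone in p: every rejected p <= every accepted p
    if (any(r$reject) && any(!r$reject)) {
      expect_lte(max(p[r$reject]), min(p[!r$reject]))
    }
  }
})

test_that("region pair correlations are symmetric with unit diagonal", {
  zt <- seq(0, 22, 2)
  df <- rbind(
    data.frame(region_label = "A", zt = zt, mean_length_um = sin(zt / 4) + 5),
    data.frame(region_label = "B", zt = zt, mean_length_um = sin(zt / 4) + 7),
    data.frame(region_label = "C", zt = zt, mean_length_um = -sin(zt / 4) + 6)
  )
  cc <- region_pair_correlations(df)
  expect_equal(diag(cc$r), c(A = 1, B = 1, C = 1))
  expect_equal(cc$r, t(cc$r))
  expect_equal(cc$r["A", "B"], 1)       # identical shape
  expect_equal(cc$r["A", "C"], -1)      # negated about the mean
  # direct covariance/sd oracle on a 12-point toy
  set.seed(42)
  x <- rnorm(12); y <- rnorm(12)
  df2 <- rbind(data.frame(region_label = "X", zt = zt, mean_length_um = x),
               data.frame(region_label = "Y", zt = zt, mean_length_um = y))
  cc2 <- region_pair_correlations(df2)
  oracle_r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(cc2$r["X", "Y"], oracle_r, tolerance = 1e-12)
  # zero-variance profile flagged
  df3 <- rbind(df2, data.frame(region_label = "Z", zt = zt, mean_length_um = 1))
  expect_warning(cc3 <- region_pair_correlations(df3), "zero-variance")
  expect_true(is.na(cc3$r["X", "Z"]))
})

test_that("cosinor recovers a noiseless cosine to machine precision", {
  t <- seq(0, 22, 2)
  y <- 5 + 2 * cos(2 * pi * (t - 6) / 24)
  f <- cosinor_fit(t, y)
  expect_equal(f$mesor, 5, tolerance = 1e-10)
  expect_equal(f$amplitude, 2, tolerance = 1e-10)
  expect_equal(f$phase, 6, tolerance = 1e-10)
  expect_lt(f$p, 1e-12)
  # constant series: amplitude 0, p ~ 1
  fc <- cosinor_fit(t, rep(4, length(t)))
  expect_equal(fc$amplitude, 0, tolerance = 1e-12)
  expect_equal(fc$p, 1)
  expect_error(cosinor_fit(c(0, 12), c(1, 2)), "3 distinct")
})

test_that("cosinor phase is equivariant to circular shifts", {
  t <- seq(0, 22, 2)
  set.seed(43)
  y <- 5 + 1.5 * cos(2 * pi * (t - 3) / 24) + rnorm(12, 0, 0.1)
  f0 <- cosinor_fit(t, y)
  for (shift in c(4, 10)) {
    fs <- cosinor_fit((t + shift) %% 24, y)
    expect_equal(fs$phase, (f0$phase + shift) %% 24, tolerance = 1e-8)
    expect_equal(fs$amplitude, f0$amplitude, tolerance = 1e-8)
  }
})
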