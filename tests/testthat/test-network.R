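test_that("connectivity normalisation divides, averages, then logs", {
  exps <- data.frame(source = c("A", "A", "A", "B"),
                     target = c("B", "B", "C", "C"),
                     projection_density = c(0.5, 0.75, 0.2, 0),
                     injection_volume = c(0.25, 0.25, 0.1, 1))
  out <- normalize_connectivity(exps, log = FALSE)
  expect_equal(out$W["A", "B"], mean(c(2, 3)))   # per-experiment then mean
  expect_equal(out$W["A", "C"], 2)
  expect_equal(out$W["B", "C"], 0)
  lg <- normalize_connectivity(exps)
  # zeros floored to smallest positive entry before log10
  expect_equal(lg$W["B", "C"], log10(2))
  expect_equal(lg$W["A", "B"], log10(2.5))
  expect_error(normalize_connectivity(transform(exps, injection_volume = 0)),
               "positive")
  # all-equal matrix stays all-equal after the monotone transform
  eq <- data.frame(source = rep(c("A", "B"), each = 2),
                   target = rep(c("B", "A"), 2),
                   projection_density = 1, injection_volume = 2)
  expect_true(length(unique(normalize_connectivity(eq)$W[
    c("A", "B"), c("A", "B")][c(2, 3)])) == 1L)
})

test_that("Louvain separates disconnected cliques and handles single nodes", {
  W <- matrix(0, 8, 8, dimnames = list(letters[1:8], letters[1:8]))
  W[1:4, 1:4] <- 1; W[5:8, 5:8] <- 1; diag(W) <- 0
  comm <- detect_communities(W, seed = 5)
  expect_length(unique(comm), 2L)
  expect_length(unique(comm[1:4]), 1L)
  expect_length(unique(comm[5:8]), 1L)
  # labels cover all regions exactly once (a partition)
  expect_identical(names(comm), letters[1:8])
  one <- matrix(0, 1, 1, dimnames = list("x", "x"))
  expect_length(detect_communities(one), 1L)
  expect_error(detect_communities(matrix(numeric(0), 0, 0)), "empty")
})

test_that("correlation edge weights follow -ln(1 - |r|) with a cap", {
  expect_equal(correlation_edge_weights(0), 0)
  expect_equal(correlation_edge_weights(0.9), -log(0.1), tolerance = 1e-12)
  r <- seq(0, 1, 0.05)
  w <- correlation_edge_weights(r)
  expect_true(all(diff(w) > 0))            # strictly increasing in |r|
  expect_equal(correlation_edge_weights(-0.9), correlation_edge_weights(0.9))
  expect_lt(correlation_edge_weights(1), Inf) # cap keeps weights finite
  expect_error(correlation_edge_weights(1.5), "-1, 1")
})

test_that("correlated fraction and percentile behave at the extremes", {
  comm <- setNames(rep(c(1, 2), each = 4), letters[1:8])
  sig <- matrix(TRUE, 8, 8, dimnames = list(letters[1:8], letters[1:8]))
  res <- correlated_fraction_percentile(sig, comm, c(1, 2), n_perm = 200,
                                        seed = 9)
  expect_equal(res$fraction, 1)
  expect_identical(res$n_pairs, 16L)       # 4 x 4 cross pairs
  expect_equal(res$percentile, 100)        # degenerate null, ties counted <=
  expect_true(all(res$null == 1))          # shuffles preserve the flag count
  expect_error(correlated_fraction_percentile(sig, comm, c(1, 3)), "no region")
})

test_that("planted enrichment is detected as a high percentile", {
  set.seed(10)
  comm <- setNames(rep(c(1, 2, 3), times = c(7, 7, 8)), paste0("R", 1:22))
  hits <- 0L
  for (s in 1:20) {
    net <- synth_connectivity(comm, w_in = 1, w_out = 0.05, sig_base = 0.1,
                              sig_enrich = list(list(pair = c(1, 2), rate = 0.5)),
                              seed = 100 + s)
    res <- correlated_fraction_percentile(net$sig, comm, c(1, 2),
                                          n_perm = 500, seed = s)
    if (res$percentile > 95) hits <- hits + 1L
  }
  expect_gte(hits, 14L) # enriched pairs sit in the upper tail most runs
})
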