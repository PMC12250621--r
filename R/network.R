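# Region connectivity networks: normalisation of projection data, Louvain
# community detection, log-scaled correlation edge weights, and the
# permutation test on the fraction of significantly correlated region
# pairs between communities.

#' Normalise projection experiments into a connectivity matrix
#'
#' Each experiment's projection density is divided by its injection
#' volume; normalised values are averaged across experiments per
#' (source, target) pair; the resulting matrix is log10-transformed after
#' flooring zeros to the smallest positive entry (the data are silent on
#' zeros, and the floor keeps the transform finite and monotone).
#'
#' @param experiments data.frame with columns `source`, `target`,
#'   `projection_density` (>= 0) and `injection_volume` (> 0).
#' @param log whether to apply the log10 transform (default TRUE).
#' @return list with `W` (region x region matrix, log scale unless
#'   `log = FALSE`) and `W_linear` (pre-log averaged matrix).
#' @export
normalize_connectivity <- function(experiments, log = TRUE) {
  df <- as.data.frame(experiments)
  stopifnot(all(c("source", "target", "projection_density",
                  "injection_volume") %in% names(df)))
  if (any(df$injection_volume <= 0)) stop("injection volumes must be positive")
  if (any(df$projection_density < 0)) stop("projection density must be >= 0")
  df$norm <- df$projection_density / df$injection_volume
  regions <- sort(unique(c(df$source, df$target)))
  W <- matrix(NA_real_, length(regions), length(regions),
              dimnames = list(regions, regions))
  agg <- stats::aggregate(norm ~ source + target, data = df, FUN = mean)
  W[cbind(match(agg$source, regions), match(agg$target, regions))] <- agg$norm
  W[is.na(W)] <- 0
  W_linear <- W
  if (log) {
    pos <- W[W > 0]
    if (length(pos)) {
      W[W == 0] <- min(pos)
      W <- log10(W)
    }
  }
  list(W = W, W_linear = W_linear, regions = regions)
}

#' Louvain community detection on a connectivity matrix
#'
#' Modularity maximisation (Louvain) on the weighted undirected graph
#' obtained by symmetrising the matrix (mean of W and t(W), diagonal
#' ignored).  Edge weights must be non-negative; matrices on a log scale
#' are shifted to a non-negative range first.  Seeded for reproducibility.
#'
#' @param W square weight matrix with region dimnames.
#' @param resolution Louvain resolution parameter (default 1).
#' @param seed RNG seed.
#' @return named integer vector of community labels, one per region.
#' @export
detect_communities <- function(W, resolution = 1, seed = 1L) {
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  if (nrow(W) == 0L) stop("empty graph")
  A <- (W + t(W)) / 2
  diag(A) <- 0
  off <- A[row(A) != col(A)]
  if (length(off) && min(off) < 0) {
    # log-scaled weights can be negative; shift to non-negative
    A <- A - min(off)
    diag(A) <- 0
  }
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, resolution = resolution)
  memb <- igraph::membership(cl)
  out <- as.integer(memb)
  names(out) <- if (!is.null(rownames(W))) rownames(W) else as.character(seq_len(nrow(W)))
  out
}

#' Log-scaled correlation edge weights
#'
#' `w = -ln(1 - min(|r|, cap))`: zero at r = 0, strictly increasing in |r|,
#' spreading the high-correlation regime; the cap (default 0.999) avoids
#' infinite weights at |r| = 1.
#'
#' @param r_matrix matrix (or vector) of Pearson correlations in [-1, 1].
#' @param cap upper bound applied to |r| before the transform.
#' @return object of the same shape with non-negative weights.
#' @export
correlation_edge_weights <- function(r_matrix, cap = 0.999) {
  if (any(abs(r_matrix) > 1 + 1e-12, na.rm = TRUE)) {
    stop("correlations must lie in [-1, 1]")
  }
  -log(1 - pmin(abs(r_matrix), cap))
}

# unordered region pairs between (or within) two communities
community_pairs <- function(communities, c1, c2) {
  regs <- names(communities)
  idx <- utils::combn(length(regs), 2L)
  ci <- communities[idx[1, ]]
  cj <- communities[idx[2, ]]
  sel <- (ci == c1 & cj == c2) | (ci == c2 & cj == c1)
  cbind(idx[1, sel], idx[2, sel])
}

#' Permutation test on the correlated fraction between two communities
#'
#' The observed statistic is the fraction of significantly correlated
#' region pairs among all pairs between communities `c1` and `c2` (within
#' one community when `c1 == c2`).  The null distribution is obtained by
#' permuting the significance flags across all region pairs (preserving
#' the total number of significant pairs) `n_perm` times; the percentile
#' of the observed fraction in the null is reported, counting ties as
#' `<=` (so `percentile = 100 * #(null <= observed) / n_perm`).
#'
#' @param sig symmetric logical matrix of pair significance (p < 0.05),
#'   with region dimnames; the diagonal is ignored.
#' @param communities named community labels (same regions as `sig`).
#' @param pair length-2 vector of community labels `c(c1, c2)`.
#' @param n_perm number of permutations (default 10000).
#' @param seed RNG seed.
#' @return list with `fraction`, `percentile`, `n_pairs` (pairs between
#'   the two communities) and `null` (the permuted fractions).
#' @export
correlated_fraction_percentile <- function(sig, communities, pair,
                                           n_perm = 10000L, seed = 1L) {
  stopifnot(is.matrix(sig), nrow(sig) == ncol(sig))
  regs <- names(communities)
  if (!is.null(rownames(sig))) sig <- sig[regs, regs]
  idx_all <- utils::combn(nrow(sig), 2L)
  flags <- sig[cbind(idx_all[1, ], idx_all[2, ])]
  between <- community_pairs(communities, pair[1], pair[2])
  if (nrow(between) == 0L) stop("no region pairs between the two communities")
  # positions of the between-community pairs in the flag vector
  key_all <- paste(idx_all[1, ], idx_all[2, ])
  key_btw <- paste(between[, 1], between[, 2])
  pos <- match(key_btw, key_all)
  obs <- mean(flags[pos])
  set.seed(seed)
  m <- length(flags)
  null <- vapply(seq_len(n_perm), function(i) {
    mean(flags[sample.int(m)][seq_along(pos)])
  }, numeric(1))
  list(fraction = obs,
       percentile = 100 * sum(null <= obs) / n_perm,
       n_pairs = length(pos), null = null)
}
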