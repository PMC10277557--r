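# Fixture builders and independent oracles used across the suite.

# Symmetric t-value matrix from an upper-triangle vector (row-major in (i, j))
sym_from_upper <- function(values, n) {
  m <- matrix(0, n, n)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  m[idx] <- values
  m[idx[, c(2, 1)]] <- values
  diag(m) <- NA_real_
  m
}

# Random symmetric "t matrix" with standard normal entries
random_tmat <- function(n, seed) {
  set.seed(seed)
  sym_from_upper(rnorm(n * (n - 1) / 2), n)
}

# fn_cohort built from a subjects x edges weight matrix (rows = subjects).
# Weights are scaled into the [-1, 1] partial-correlation range when needed;
# the pooled t is invariant to a common scale, and the scaled matrix is kept
# in the "W" attribute for oracle computations on identical inputs.
cohort_from_edges <- function(W, labels, n_rois) {
  s <- max(abs(W))
  if (s > 1) W <- W / (s * 1.01)
  nets <- lapply(seq_len(nrow(W)), function(s) sym_from_upper(W[s, ], n_rois))
  out <- fn_cohort(nets, sprintf("S%02d", seq_len(nrow(W))), labels)
  attr(out, "W") <- W
  out
}

# Percolation threshold by exhaustive scan over sorted distinct t values:
# the largest threshold whose suprathreshold graph (t >= tau) connects all
# nodes. Independent of the maximum-spanning-tree route.
percolation_scan_oracle <- function(tmat) {
  n <- nrow(tmat)
  tv <- tmat[upper.tri(tmat)]
  idx <- which(upper.tri(tmat), arr.ind = TRUE)
  connected_at <- function(tau) {
    keep <- which(is.finite(tv) & tv >= tau)
    if (length(keep) < n - 1) {
      return(FALSE)
    }
    g <- igraph::make_empty_graph(n = n, directed = FALSE)
    g <- igraph::add_edges(g, t(idx[keep, , drop = FALSE]))
    igraph::components(g)$no == 1
  }
  for (tau in sort(unique(tv[is.finite(tv)]), decreasing = TRUE)) {
    if (connected_at(tau)) {
      return(tau)
    }
  }
  stop("no connecting threshold")
}

# Exhaustive permutation FWE p-value by a slow independent route: for every
# subset of size n_first (the contrast-favored group), per-edge stats::t.test
# and igraph components, max component intensity; p = fraction strictly above
# the observed intensity.
exhaustive_perm_oracle <- function(W, n_first, tau, obs_intensity, n_rois) {
  idx <- which(upper.tri(matrix(0, n_rois, n_rois)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  subsets <- utils::combn(nrow(W), n_first, simplify = FALSE)
  null <- vapply(subsets, function(first_idx) {
    tv <- vapply(seq_len(ncol(W)), function(e) {
      unname(stats::t.test(W[first_idx, e], W[-first_idx, e],
                           var.equal = TRUE)$statistic)
    }, numeric(1))
    keep <- which(tv >= tau - 1e-9 * max(1, abs(tau))) # tolerant threshold tie

    if (!length(keep)) {
      return(0)
    }
    g <- igraph::make_empty_graph(n = n_rois, directed = FALSE)
    g <- igraph::add_edges(g, t(idx[keep, , drop = FALSE]))
    memb <- igraph::components(g)$membership
    max(tapply(tv[keep], memb[idx[keep, 1]], sum))
  }, numeric(1))
  # same tolerance-aware strictly-greater rule as the package counting
  mean(null > obs_intensity + 1e-8 * max(1, abs(obs_intensity)))
}

# Connected dysconnected-network fixture with exactly n_nodes touched nodes
# and n_edges edges: a path over the nodes plus chords in deterministic order.
make_connected_dysconn <- function(n_edges, n_nodes, n_rois, threshold = 2) {
  stopifnot(n_edges >= n_nodes - 1, n_nodes <= n_rois)
  edges <- cbind(seq_len(n_nodes - 1), seq_len(n_nodes - 1) + 1L)
  extra_needed <- n_edges - nrow(edges)
  if (extra_needed > 0) {
    chords <- expand.grid(i = seq_len(n_nodes), j = seq_len(n_nodes))
    chords <- as.matrix(chords[chords$j > chords$i + 1L, c("i", "j")])
    chords <- chords[order(chords[, 1], chords[, 2]), , drop = FALSE]
    edges <- rbind(edges, chords[seq_len(extra_needed), , drop = FALSE])
  }
  tmat <- matrix(-1, n_rois, n_rois)
  tmat[edges] <- threshold + 0.5
  tmat[edges[, c(2, 1)]] <- threshold + 0.5
  diag(tmat) <- NA_real_
  comps <- suprathreshold_components(tmat, threshold)
  stopifnot(length(comps) == 1L)
  comps[[1]]
}

# Balanced toy where relabeling the test subject (index 1) leaves the
# edgewise t-matrix unchanged: subject 1's weights equal both group means
# exactly (dyadic values, so group means are exact in floating point).
symmetric_toy_cohort <- function(n_rois = 4) {
  n_edges <- n_rois * (n_rois - 1) / 2
  mu <- (seq_len(n_edges) %% 3 + 1) * 0.125
  a <- 0.0625
  W <- rbind(mu, mu + a, mu - a, mu + a, mu - a)
  cohort_from_edges(W, c("ECP", "ECP", "ECP", "LCP", "LCP"), n_rois)
}

# Small planted-effect edge-level cohort for classifier tests
planted_edge_cohort <- function(seed, n_ecp = 8, n_lcp = 8, n_rois = 12,
                                n_planted = 14, effect_size = 0.3,
                                noise_sd = 0.1) {
  simulate_edge_cohort(cohort_spec(
    n_ecp = n_ecp, n_lcp = n_lcp, n_rois = n_rois, n_planted = n_planted,
    effect_size = effect_size, noise_sd = noise_sd, seed = seed
  ))
}
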