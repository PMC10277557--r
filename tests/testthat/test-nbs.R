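# NBS core: edgewise t-statistics, suprathreshold components, percolation
# threshold, permutation FWE p-values, component selection.

test_that("edgewise t matches the pooled-t hand evaluation and a t.test oracle", {
  # 3 ROIs, edge (1,2) carries {0,2} for ECP vs {3,5} for LCP
  W <- rbind(c(0, 0.1, 0.2), c(2, 0.3, 0.1), c(3, 0.2, 0.15), c(5, 0.4, 0.05))
  co <- cohort_from_edges(W, c("ECP", "ECP", "LCP", "LCP"), 3)
  tm <- edge_t_stats(co, contrast = "ECP_GT_LCP")
  # the pooled t is invariant to the common rescaling into [-1, 1]
  expect_equal(tm$values[1, 2], -3 / sqrt(2), tolerance = 1e-12)
  # generic t.test oracle on every edge (same rescaled weights)
  Ws <- attr(co, "W")
  for (e in 1:3) {
    oracle <- unname(stats::t.test(Ws[1:2, e], Ws[3:4, e], var.equal = TRUE)$statistic)
    expect_equal(tm$t_vector[e], oracle, tolerance = 1e-10)
  }
  expect_equal(tm$values, t(tm$values)) # symmetry (NA diagonal matches itself)
  # contrast flip negates the matrix elementwise
  tm_flip <- edge_t_stats(co, contrast = "ECP_LT_LCP")
  expect_equal(tm_flip$t_vector, -tm$t_vector, tolerance = 1e-12)
})

test_that("identical groups give zero t and degenerate edges get the -Inf sentinel", {
  # 3 ROIs -> 3 edges; edge 2 is constant across all subjects
  W <- rbind(c(0, 1, 0.5), c(2, 1, 0.1), c(0, 1, 0.3), c(2, 1, 0.2))
  co <- cohort_from_edges(W, c("ECP", "ECP", "LCP", "LCP"), 3)
  expect_message(tm <- edge_t_stats(co), "degenerate")
  expect_equal(tm$t_vector[1], 0)
  expect_identical(tm$t_vector[2], -Inf)
  # fewer than 2 per group errors
  co3 <- cohort_from_edges(W[1:3, ], c("ECP", "ECP", "LCP"), 3)
  expect_error(edge_t_stats(co3), "at least 2")
})

test_that("welch option changes the statistic under unequal variances", {
  set.seed(8)
  W <- rbind(matrix(rnorm(3 * 6, sd = 0.2), 3), matrix(rnorm(4 * 6, sd = 1.5), 4))
  co <- cohort_from_edges(W, c(rep("ECP", 3), rep("LCP", 4)), 4)
  t_pooled <- edge_t_stats(co, var_equal = TRUE)$t_vector
  t_welch <- edge_t_stats(co, var_equal = FALSE)$t_vector
  Ws <- attr(co, "W")
  oracle <- unname(stats::t.test(Ws[1:3, 1], Ws[4:7, 1], var.equal = FALSE)$statistic)
  expect_equal(t_welch[1], oracle, tolerance = 1e-10)
  expect_false(isTRUE(all.equal(t_pooled, t_welch)))
})

test_that("suprathreshold components match exhaustive enumeration on a 3-node toy", {
  tmat <- sym_from_upper(c(3, 2, 1), 3) # t(1,2)=3, t(1,3)=2, t(2,3)=1
  comps <- suprathreshold_components(tmat, 2)
  expect_length(comps, 1)
  expect_equal(comps[[1]]$edges, cbind(i = c(1L, 1L), j = c(2L, 3L)))
  expect_equal(comps[[1]]$intensity, 5)
  expect_equal(comps[[1]]$n_edges, 2)
  # threshold above the maximum: nothing survives
  expect_length(suprathreshold_components(tmat, 3.5), 0)
  # threshold below the minimum: one complete-graph component
  all_comp <- suprathreshold_components(tmat, 0)
  expect_length(all_comp, 1)
  expect_equal(all_comp[[1]]$n_edges, 3)
  # two separate components
  tmat2 <- sym_from_upper(c(5, -1, -1, -1, -1, 4), 4) # edges (1,2) and (3,4)
  comps2 <- suprathreshold_components(tmat2, 3)
  expect_length(comps2, 2)
  expect_equal(comps2[[1]]$edges[1, ], c(i = 1L, j = 2L))
  expect_equal(comps2[[2]]$edges[1, ], c(i = 3L, j = 4L))
})

test_that("percolation threshold solves the 3-node toy and asserts disconnection above", {
  tmat <- sym_from_upper(c(3, 2, 1), 3)
  pt <- percolation_threshold(tmat)
  expect_equal(pt$threshold, 2)
  expect_equal(pt$mcc$edges, cbind(i = c(1L, 1L), j = c(2L, 3L)))
  expect_equal(pt$mcc$nodes, 1:3)
  # all edges equal: threshold is that value and the MCC is the complete graph
  flat <- sym_from_upper(rep(1.5, 6), 4)
  ptf <- percolation_threshold(flat)
  expect_equal(ptf$threshold, 1.5)
  expect_equal(ptf$mcc$n_edges, 6)
})

test_that("spanning-tree bottleneck equals the exhaustive scan oracle on random matrices", {
  for (seed in 1:100) {
    tmat <- random_tmat(12, seed)
    pt <- percolation_threshold(tmat)
    expect_equal(pt$threshold, percolation_scan_oracle(tmat), tolerance = 0)
    expect_equal(pt$mcc$nodes, 1:12) # MCC spans all nodes
  }
})

test_that("percolation fails loudly when sentinel edges isolate a node", {
  tmat <- sym_from_upper(c(3, -Inf, -Inf), 3) # node 3 unreachable on finite edges
  expect_error(percolation_threshold(tmat), "isolated node set: 3")
})

test_that("union-find max component intensity agrees with the igraph route", {
  pairs <- chronet:::edge_pairs(9)
  for (seed in 1:25) {
    tmat <- random_tmat(9, seed)
    tv <- tmat[cbind(pairs[, 1], pairs[, 2])]
    tau <- stats::quantile(tv, 0.6)
    comps <- suprathreshold_components(tmat, tau)
    keep <- which(tv >= tau)
    uf <- chronet:::max_component_intensity(pairs[keep, 1], pairs[keep, 2], tv[keep], 9)
    expect_equal(uf, max(vapply(comps, function(d) d$intensity, numeric(1))),
                 tolerance = 1e-12)
  }
})

test_that("sampled permutation p with full enumeration equals the exhaustive oracle", {
  set.seed(15)
  W <- matrix(rnorm(6 * 6, sd = 0.3), 6, 6) # 3v3 subjects, 4 ROIs -> 6 edges
  co <- cohort_from_edges(W, c(rep("ECP", 3), rep("LCP", 3)), 4)
  tm <- edge_t_stats(co, contrast = "ECP_GT_LCP")
  pt <- percolation_threshold(tm)
  # choose(6, 3) = 20 distinct assignments <= n_perm: enumeration kicks in
  p_impl <- permutation_pvalue(co, contrast = "ECP_GT_LCP", tau = pt$threshold,
                               observed = pt$mcc, n_perm = 100, seed = 1)
  p_oracle <- exhaustive_perm_oracle(attr(co, "W"), 3, pt$threshold,
                                     pt$mcc$intensity, 4)
  expect_identical(p_impl, p_oracle)
  # and it is seed-invariant because enumeration replaced sampling
  p_impl2 <- permutation_pvalue(co, contrast = "ECP_GT_LCP", tau = pt$threshold,
                                observed = pt$mcc, n_perm = 100, seed = 999)
  expect_identical(p_impl2, p_impl)
})

test_that("p-value counting rules behave at the extremes", {
  set.seed(16)
  co <- planted_edge_cohort(16, n_ecp = 5, n_lcp = 5, n_rois = 8, n_planted = 10,
                            effect_size = 0.8, noise_sd = 0.05)
  fit <- run_nbs(co, contrast = "ECP_GT_LCP", n_perm = 100, seed = 2)
  # observed intensity dominates every null draw
  expect_identical(fit$network$p_value, 0)
  # conservative mode can never return 0
  fit_c <- run_nbs(co, contrast = "ECP_GT_LCP", n_perm = 100, seed = 2,
                   p_mode = "conservative")
  expect_gt(fit_c$network$p_value, 0)
})

test_that("permutation p is invariant to relabeling ROI indices", {
  set.seed(17)
  W <- matrix(rnorm(8 * 10, sd = 0.3), 8, 10) # 5 ROIs
  co <- cohort_from_edges(W, c(rep("ECP", 4), rep("LCP", 4)), 5)
  perm <- c(3, 5, 1, 2, 4) # node permutation
  co_perm <- fn_cohort(lapply(co$networks, function(m) m[perm, perm]),
                       co$subject_id, co$label)
  f1 <- run_nbs(co, threshold = 0.8, n_perm = 150, seed = 4)
  f2 <- run_nbs(co_perm, threshold = 0.8, n_perm = 150, seed = 4)
  # candidate p-values and intensities are graph invariants of the relabeling
  stats_of <- function(f) {
    m <- cbind(vapply(f$candidates, function(d) d$p_value, numeric(1)),
               vapply(f$candidates, function(d) d$intensity, numeric(1)))
    m[order(m[, 1], m[, 2]), , drop = FALSE]
  }
  expect_equal(stats_of(f1), stats_of(f2), tolerance = 1e-12)
})

test_that("component selection follows p, then edge count, then smallest ROI", {
  d1 <- make_connected_dysconn(5, 5, 10)
  d2 <- make_connected_dysconn(9, 8, 10)
  d1$p_value <- 0.03
  d2$p_value <- 0.2
  expect_identical(select_component(list(d1, d2)), d1)
  d2$p_value <- 0.03
  expect_identical(select_component(list(d1, d2)), d2) # 9 edges beats 5
  # full tie: component containing the smallest ROI index wins
  a <- suprathreshold_components(sym_from_upper(c(5, -1, -1, -1, -1, 4), 4), 3)
  a[[1]]$p_value <- a[[2]]$p_value <- 0.1
  a[[1]]$t_values <- a[[2]]$t_values # equalize intensity irrelevantly
  pick <- select_component(a)
  expect_equal(min(pick$nodes), 1)
  expect_identical(select_component(list())$no_component, TRUE)
})

test_that("run_nbs composes: power on planted effects, no component above max t", {
  # strong planted effect: FWE p < 0.05 in nearly all replicates
  hits <- 0L
  n_rep <- 50
  for (r in seq_len(n_rep)) {
    co <- planted_edge_cohort(60000 + r)
    fit <- run_nbs(co, contrast = "ECP_GT_LCP", threshold = "percolation",
                   n_perm = 200, seed = r)
    hits <- hits + (fit$network$p_value < 0.05)
  }
  expect_gte(hits / n_rep, 0.9)
  # fixed threshold above the maximum t: the no-component sentinel
  co <- planted_edge_cohort(1)
  tmax <- max(edge_t_stats(co)$t_vector)
  fit <- run_nbs(co, threshold = tmax + 1, n_perm = 50, seed = 1)
  expect_true(fit$network$no_component)
  expect_equal(fit$network$n_edges, 0)
})

test_that("under the exchangeable null the FWE p-value is approximately uniform", {
  pvals <- numeric(200)
  for (r in 1:200) {
    co <- simulate_edge_cohort(cohort_spec(
      n_ecp = 8, n_lcp = 8, n_rois = 10, n_planted = 10,
      effect_size = 0, noise_sd = 0.1, seed = 70000 + r
    ))
    fit <- run_nbs(co, threshold = "percolation", n_perm = 200, seed = r)
    pvals[r] <- fit$network$p_value
  }
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("at the global minimum t exactly one candidate exists: the complete graph", {
  tmat <- random_tmat(7, 5)
  tv <- tmat[upper.tri(tmat)]
  comps <- suprathreshold_components(tmat, min(tv))
  expect_length(comps, 1)
  expect_equal(comps[[1]]$n_edges, choose(7, 2))
})
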