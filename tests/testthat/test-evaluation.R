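# Evaluation metrics, sweeps, stability, degree conventions.

test_that("outcome metric arithmetic follows the stated definitions", {
  true <- c(rep("ECP", 4), rep("LCP", 6))
  assigned <- c("ECP", "ECP", "UNCLEAR", "LCP", rep("LCP", 5), "UNCLEAR")
  ev <- evaluation_summary(true, assigned)
  expect_equal(ev$accuracy, 7 / 10)
  expect_equal(ev$misclassification, 1 / 10)
  expect_equal(ev$unclear, 2 / 10)
  expect_equal(ev$sensitivity, 2 / 4)
  expect_equal(ev$specificity, 5 / 6)
  expect_equal(ev$balanced_accuracy, (2 / 4 + 5 / 6) / 2)
  expect_equal(ev$accuracy + ev$misclassification + ev$unclear, 1, tolerance = 1e-12)
  # all unclear
  ev0 <- evaluation_summary(true, rep("UNCLEAR", 10))
  expect_equal(ev0$accuracy, 0)
  expect_equal(ev0$unclear, 1)
  expect_equal(ev0$misclassification, 0)
})

test_that("step counts tabulate deciding steps by true group", {
  ev <- evaluation_summary(
    true_label = c("ECP", "ECP", "LCP", "LCP", "LCP"),
    assigned_label = c("ECP", "UNCLEAR", "LCP", "LCP", "UNCLEAR"),
    deciding_step = c(1L, 1L, 2L, 3L, NA)
  )
  expect_equal(ev$step_counts["ECP", "1"], 2)
  expect_equal(ev$step_counts["LCP", "2"], 1)
  expect_equal(ev$step_counts["LCP", "3"], 1)
  expect_equal(ev$step_counts["LCP", "none"], 1)
})

test_that("percent definite matches the printed-table convention", {
  labels <- system.file("extdata", "session_labels.tsv", package = "chronet")
  tab <- read.delim(labels, stringsAsFactors = FALSE, na.strings = "NA")
  expect_equal(percent_definite(tab$afternoon_ecp_lt_lcp), 29.7)
  expect_equal(percent_definite(tab$morning_ecp_lt_lcp), 23.7)
  expect_equal(percent_definite(tab$evening_ecp_gt_lcp), 100)
  expect_equal(percent_definite(tab$evening_ecp_lt_lcp), 0)
  expect_equal(percent_definite(tab$afternoon_ecp_gt_lcp), 2.7)
  expect_error(percent_definite(c(NA, NA)), "all entries")
})

test_that("degree summaries use the full parcellation as denominator", {
  net <- make_connected_dysconn(n_edges = 20, n_nodes = 15, n_rois = 30)
  ds <- network_degree_summary(net, 30)
  expect_equal(ds$mean_degree, 2 * 20 / 30)
  expect_equal(sum(ds$degrees), 2 * 20)
  expect_equal(mean(ds$degrees), ds$mean_degree)
  # population sd convention
  expect_equal(ds$sd_degree, sqrt(mean((ds$degrees - ds$mean_degree)^2)))
  expect_equal(ds$max_degree, max(ds$degrees))
  expect_true(all(ds$degrees[ds$max_nodes] == ds$max_degree))
})

test_that("leave-one-out evaluation enforces group sizes and conserves fractions", {
  co <- planted_edge_cohort(11, n_ecp = 3, n_lcp = 5)
  expect_error(evaluate_loo(planted_edge_cohort(11, n_ecp = 3, n_lcp = 2),
                            classifier_config(n_perm = 20)), "at least 3")
  ev <- evaluate_loo(co, classifier_config(n_perm = 50, seed = 2))
  expect_equal(ev$accuracy + ev$misclassification + ev$unclear, 1, tolerance = 1e-12)
  expect_equal(nrow(ev$per_subject), 8)
})

test_that("threshold sweep: beyond-max threshold is all unclear, max dominates, one-sidedness", {
  co <- planted_edge_cohort(12)
  grid <- c(0.5, 1.5, 3, 8, 30)
  sw <- sweep_threshold(co, contrast = "ECP_GT_LCP", grid = grid,
                        n_perm = 60, seed = 5)
  expect_equal(nrow(sw$table), length(grid))
  # fractions conserve at every grid point
  sums <- sw$table$accuracy + sw$table$misclassification + sw$table$unclear
  expect_equal(sums, rep(1, length(grid)), tolerance = 1e-12)
  # far beyond any observed t nothing survives: everyone unclear
  expect_equal(sw$table$unclear[length(grid)], 1)
  # the best grid accuracy dominates any single pre-chosen threshold
  expect_gte(max(sw$table$accuracy), sw$table$accuracy[2])
  expect_true(is.finite(sw$percolation_true))
})

test_that("non-zero sweep accuracy occurs only under the planted direction", {
  spec <- cohort_spec(n_ecp = 8, n_lcp = 10, n_rois = 12, n_timepoints = 300,
                      n_planted = 20, effect_size = 0.30, seed = 1)
  nets <- build_networks(simulate_cohort(spec), 0.05)
  grid <- seq(0, 4.5, by = 0.25)
  sw_match <- sweep_threshold(nets, contrast = "ECP_GT_LCP", grid = grid,
                              n_perm = 100, seed = 5)
  sw_op <- sweep_threshold(nets, contrast = "ECP_LT_LCP", grid = grid,
                           n_perm = 100, seed = 5)
  expect_true(any(sw_match$table$accuracy > 0.5))
  expect_true(all(sw_op$table$accuracy == 0))
})

test_that("alpha sweep: all unclear at zero, plateau above the maximum p-value", {
  co <- planted_edge_cohort(13, n_ecp = 5, n_lcp = 6, n_rois = 10)
  cfg <- classifier_config(n_perm = 80, seed = 4)
  sw <- sweep_alpha(co, cfg, grid = c(0, 0.02, 0.05, 0.3, 0.6, 0.9, 1))
  expect_equal(sw$table$unclear[1], 1) # alpha = 0: nothing significant
  expect_equal(sw$table$accuracy[1], 0)
  # plateau: above the largest of all subjects' four p-values the outcome is frozen
  all_p <- unlist(lapply(sw$quads, function(q) {
    c(q$net_E_tE$p_value, q$net_L_tL$p_value, q$net_E_tL$p_value, q$net_L_tE$p_value)
  }))
  above <- which(sw$grid > max(all_p, na.rm = TRUE))
  if (length(above) > 1) {
    expect_equal(sw$table$accuracy[above], rep(sw$table$accuracy[above[1]], length(above)))
  }
  # conservation across the whole grid
  sums <- sw$table$accuracy + sw$table$misclassification + sw$table$unclear
  expect_equal(sums, rep(1, nrow(sw$table)), tolerance = 1e-12)
})

test_that("alpha sweep at 0.05 reproduces the plain leave-one-out summary", {
  co <- planted_edge_cohort(14, n_ecp = 5, n_lcp = 5, n_rois = 10)
  cfg <- classifier_config(alpha = 0.05, n_perm = 60, seed = 8)
  sw <- sweep_alpha(co, cfg, grid = c(0.01, 0.05, 0.2))
  ev <- evaluate_loo(co, cfg)
  expect_equal(sw$table$accuracy[2], ev$accuracy)
  expect_equal(sw$table$unclear[2], ev$unclear)
  expect_equal(sw$evaluations[[2]]$per_subject$assigned_label,
               ev$per_subject$assigned_label)
})

test_that("stability analysis produces one conserving row per removed subject", {
  co <- planted_edge_cohort(15, n_ecp = 4, n_lcp = 5, n_rois = 8, n_planted = 10)
  st <- stability_analysis(co, classifier_config(n_perm = 40, seed = 6))
  expect_equal(nrow(st$table), 9)
  sums <- st$table$accuracy + st$table$unclear + st$table$misclassification
  expect_equal(sums, rep(1, 9), tolerance = 1e-12)
  expect_equal(st$means["accuracy"], mean(st$table$accuracy), ignore_attr = TRUE)
  # re-running one row reproduces it exactly
  r3 <- evaluate_loo(co[-3], classifier_config(n_perm = 40, seed = 6))
  expect_equal(r3$accuracy, st$table$accuracy[3])
  expect_identical(r3$per_subject, st$evaluations[[3]]$per_subject)
  expect_error(stability_analysis(planted_edge_cohort(15, n_ecp = 3, n_lcp = 5),
                                  classifier_config(n_perm = 20)), "at least 4")
})

test_that("null-cohort stability rows are statistically homogeneous", {
  # with no planted effect, removing any single subject should neither shift
  # the dominant (unclear) outcome rate beyond binomial noise nor manufacture
  # a high-performing classifier
  for (seed in c(101, 202, 303)) {
    co <- simulate_edge_cohort(cohort_spec(
      n_ecp = 8, n_lcp = 10, n_rois = 10, n_planted = 10,
      effect_size = 0, noise_sd = 0.1, seed = seed
    ))
    st <- stability_analysis(co, classifier_config(n_perm = 100, seed = seed))
    n_eval <- 17 # subjects per row after one removal
    m <- mean(st$table$unclear)
    # binomial sd with a half-subject floor against pure discreteness
    s <- max(sqrt(m * (1 - m) / n_eval), 0.5 / n_eval)
    expect_true(all(abs(st$table$unclear - m) <= 3 * s))
    expect_lte(max(st$table$accuracy), 0.3)
  }
})
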