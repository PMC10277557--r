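# Network-based statistic: edgewise contrast t-statistics, suprathreshold
# connected components (dysconnected networks), percolation-threshold /
# minimum-connected-component search, permutation familywise-error p-values,
# and the multi-component selection rule.

CONTRASTS <- c("ECP_GT_LCP", "ECP_LT_LCP")

#' @noRd
check_contrast <- function(contrast) {
  contrast <- toupper(contrast)
  contrast <- switch(contrast,
    "ECP>LCP" = "ECP_GT_LCP",
    "ECP<LCP" = "ECP_LT_LCP",
    contrast
  )
  match.arg(contrast, CONTRASTS)
}

# Group favored by the contrast: its mean goes first in the t numerator,
# so suprathreshold always means evidence for the contrast's direction.
favored_group <- function(contrast) {
  if (contrast == "ECP_GT_LCP") "ECP" else "LCP"
}

# Pooled-variance two-sample t per edge, vectorized over edges.
# W: subjects x edges; first: logical vector marking the favored group.
# Degenerate zero-variance edges get -Inf (can never be suprathreshold).
edge_t_vector <- function(W, first, var_equal = TRUE) {
  n1 <- sum(first)
  n2 <- sum(!first)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 subjects for the edgewise t-test")
  X1 <- W[first, , drop = FALSE]
  X2 <- W[!first, , drop = FALSE]
  m1 <- colMeans(X1)
  m2 <- colMeans(X2)
  ss1 <- pmax(colSums(X1 * X1) - n1 * m1^2, 0)
  ss2 <- pmax(colSums(X2 * X2) - n2 * m2^2, 0)
  if (var_equal) {
    sp2 <- (ss1 + ss2) / (n1 + n2 - 2)
    denom <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    denom <- sqrt(ss1 / (n1 - 1) / n1 + ss2 / (n2 - 1) / n2)
  }
  tv <- (m1 - m2) / denom
  tv[denom == 0] <- -Inf
  tv
}

#' Edgewise one-sided two-sample t-statistic matrix under a group contrast
#'
#' For every off-diagonal ROI pair, the pooled-variance two-sample t-statistic
#' comparing mean edge weights, with the contrast-favored group's mean first
#' in the numerator (ECP for `ECP_GT_LCP`, LCP for `ECP_LT_LCP`) and
#' `n_ECP + n_LCP - 2` degrees of freedom. Edges with zero pooled variance are
#' degenerate and carry a `-Inf` sentinel so they can never be suprathreshold.
#'
#' @param cohort an [fn_cohort()].
#' @param labels optional label vector overriding `cohort$label` (used to
#'   hypothesize a held-out subject's label).
#' @param contrast `"ECP_GT_LCP"` or `"ECP_LT_LCP"`.
#' @param var_equal pooled-variance Student t (default) or Welch when `FALSE`.
#' @return An object of class `tstat_matrix`: list with `values` (symmetric
#'   N x N, `NA` diagonal), `n_first`, `n_second`, `contrast`.
#' @export
edge_t_stats <- function(cohort, labels = NULL, contrast = "ECP_GT_LCP", var_equal = TRUE) {
  stopifnot(inherits(cohort, "fn_cohort"))
  contrast <- check_contrast(contrast)
  labels <- if (is.null(labels)) cohort$label else as.character(labels)
  stopifnot(length(labels) == length(cohort$networks))
  first <- labels == favored_group(contrast)
  W <- cohort_edge_matrix(cohort)
  tv <- edge_t_vector(W, first, var_equal = var_equal)
  n_deg <- sum(!is.finite(tv))
  if (n_deg > 0) {
    message(n_deg, " degenerate zero-variance edge(s) set to -Inf")
  }
  structure(
    list(
      values = edges_to_matrix(tv, cohort$n_rois),
      t_vector = tv,
      n_first = sum(first),
      n_second = sum(!first),
      n_rois = cohort$n_rois,
      contrast = contrast
    ),
    class = "tstat_matrix"
  )
}

#' @export
print.tstat_matrix <- function(x, ...) {
  fin <- x$t_vector[is.finite(x$t_vector)]
  cat("Edgewise t-statistic matrix (", x$n_rois, " x ", x$n_rois, "), contrast ",
      x$contrast, ", groups ", x$n_first, "/", x$n_second, "\n",
      "  t range: [", format(min(fin), digits = 4), ", ",
      format(max(fin), digits = 4), "]\n", sep = "")
  invisible(x)
}

tstat_vector <- function(tmat) {
  if (inherits(tmat, "tstat_matrix")) {
    return(tmat$t_vector)
  }
  tmat <- as.matrix(tmat)
  pairs <- edge_pairs(nrow(tmat))
  tmat[pairs]
}

tstat_n_rois <- function(tmat) {
  if (inherits(tmat, "tstat_matrix")) tmat$n_rois else nrow(as.matrix(tmat))
}

new_dysconn <- function(edges, t_values, threshold, n_rois,
                        p_value = NA_real_, label_context = NA_character_,
                        subject_context = NA_character_) {
  edges <- matrix(as.integer(edges), ncol = 2)
  colnames(edges) <- c("i", "j")
  ord <- order(edges[, 1], edges[, 2])
  edges <- edges[ord, , drop = FALSE]
  t_values <- t_values[ord]
  structure(
    list(
      edges = edges,
      t_values = t_values,
      nodes = sort(unique(as.integer(edges))),
      threshold = threshold,
      n_edges = nrow(edges),
      intensity = sum(t_values),
      p_value = p_value,
      n_rois = n_rois,
      label_context = label_context,
      subject_context = subject_context,
      no_component = FALSE
    ),
    class = "dysconn"
  )
}

#' Sentinel for the absence of any suprathreshold component
#'
#' Returned (inside results) when no edge survives a fixed threshold. It has
#' zero edges, zero intensity, and an unset p-value; the classifier treats it
#' as non-significant.
#'
#' @param threshold the threshold at which no edge survived.
#' @param n_rois parcellation size.
#' @return A `dysconn` object flagged as `no_component`.
#' @export
no_component <- function(threshold = NA_real_, n_rois = NA_integer_) {
  out <- new_dysconn(matrix(integer(0), ncol = 2), numeric(0), threshold, n_rois)
  out$no_component <- TRUE
  out
}

#' @export
print.dysconn <- function(x, ...) {
  if (isTRUE(x$no_component)) {
    cat("Dysconnected network: NO COMPONENT (no suprathreshold edge at t >= ",
        format(x$threshold, digits = 4), ")\n", sep = "")
    return(invisible(x))
  }
  cat("Dysconnected network: ", x$n_edges, " edges over ", length(x$nodes),
      " nodes (parcellation N = ", x$n_rois, ")\n",
      "  threshold t >= ", format(x$threshold, digits = 4),
      ", intensity = ", format(x$intensity, digits = 6),
      if (!is.na(x$p_value)) paste0(", FWE p = ", format(x$p_value, digits = 4)) else ", p unset",
      "\n", sep = "")
  invisible(x)
}

suprathreshold_graph <- function(tv, pairs, tau, n_rois) {
  keep <- which(is.finite(tv) & tv >= tau)
  g <- igraph::make_empty_graph(n = n_rois, directed = FALSE)
  if (length(keep)) {
    g <- igraph::add_edges(g, t(pairs[keep, , drop = FALSE]))
    igraph::E(g)$t <- tv[keep]
  }
  g
}

#' Connected components of suprathreshold edges
#'
#' Builds the graph of edges with `t >= tau` (inclusive) and returns every
#' connected component containing at least one edge as a candidate
#' dysconnected network (p-values unset). An empty list is returned when no
#' edge survives.
#'
#' @param tmat a `tstat_matrix` (or plain symmetric matrix of t-values).
#' @param tau finite threshold.
#' @return List of `dysconn` objects, ordered by their smallest ROI index.
#' @export
suprathreshold_components <- function(tmat, tau) {
  stopifnot(is.finite(tau))
  tv <- tstat_vector(tmat)
  n_rois <- tstat_n_rois(tmat)
  pairs <- edge_pairs(n_rois)
  keep <- which(is.finite(tv) & tv >= tau)
  if (!length(keep)) {
    return(list())
  }
  g <- suprathreshold_graph(tv, pairs, tau, n_rois)
  comp <- igraph::components(g)$membership
  edge_comp <- comp[pairs[keep, 1]]
  out <- lapply(split(keep, edge_comp), function(kk) {
    new_dysconn(pairs[kk, , drop = FALSE], tv[kk], tau, n_rois)
  })
  out <- unname(out)
  out[order(vapply(out, function(d) min(d$nodes), integer(1)))]
}

#' Percolation threshold and minimum connected component
#'
#' The percolation threshold is the highest t-statistic threshold at which
#' the suprathreshold graph still connects all N ROIs; any strictly higher
#' threshold isolates at least one ROI. It equals the minimum edge value
#' along a maximum(-bottleneck) spanning tree of the t-matrix. The network of
#' suprathreshold edges at this threshold is the minimum connected component
#' (MCC): the sparsest suprathreshold network spanning every ROI.
#'
#' @param tmat a `tstat_matrix` (or plain symmetric matrix of t-values).
#' @return List with `threshold` (the percolation threshold) and `mcc` (a
#'   `dysconn` spanning all N nodes, p-value unset).
#' @export
percolation_threshold <- function(tmat) {
  tv <- tstat_vector(tmat)
  n_rois <- tstat_n_rois(tmat)
  if (n_rois < 2) stop("percolation threshold needs at least 2 nodes")
  pairs <- edge_pairs(n_rois)
  fin <- which(is.finite(tv))
  g <- igraph::make_empty_graph(n = n_rois, directed = FALSE)
  if (length(fin)) {
    g <- igraph::add_edges(g, t(pairs[fin, , drop = FALSE]))
    igraph::E(g)$weight <- -tv[fin] # negate: max spanning tree via min spanning tree
  }
  comp <- igraph::components(g)
  if (comp$no > 1) {
    sizes <- comp$csize
    small <- which(comp$membership != which.max(sizes))
    stop("graph of finite-t edges is disconnected; isolated node set: ",
         paste(small, collapse = ", "))
  }
  # maximum spanning tree = minimum spanning tree on negated weights;
  # its bottleneck (minimum) edge value is the percolation threshold
  mst <- igraph::mst(g)
  mst_t <- -igraph::E(mst)$weight
  tau <- min(mst_t)
  comps <- suprathreshold_components(tmat, tau)
  stopifnot(length(comps) >= 1)
  mcc <- comps[[which(vapply(comps, function(d) length(d$nodes), integer(1)) == n_rois)]]
  # direct assertion: the next strictly larger distinct threshold disconnects
  above <- tv[is.finite(tv) & tv > tau]
  if (length(above)) {
    nxt <- min(above)
    g2 <- suprathreshold_graph(tv, pairs, nxt, n_rois)
    stopifnot(igraph::components(g2)$no > 1)
  }
  list(threshold = tau, mcc = mcc)
}

# Permutation assignments of the favored group: exhaustive enumeration when
# the number of distinct assignments fits within n_perm, otherwise seeded
# uniform sampling with replacement. Returns a list of index vectors.
perm_assignments <- function(n_subjects, n_first, n_perm, seed) {
  n_distinct <- choose(n_subjects, n_first)
  if (n_distinct <= n_perm) {
    asgn <- utils::combn(n_subjects, n_first, simplify = FALSE)
    attr(asgn, "exhaustive") <- TRUE
    return(asgn)
  }
  asgn <- with_seed(seed, replicate(n_perm, sample.int(n_subjects, n_first), simplify = FALSE))
  attr(asgn, "exhaustive") <- FALSE
  asgn
}

# Null distribution of the maximum component intensity at threshold tau:
# for each permuted assignment of the favored group, recompute the edgewise
# t-vector (vectorized across permutations), threshold at tau, and take the
# maximum connected-component intensity (0 if no edge survives).
null_max_intensity <- function(W, n_first, tau, n_perm, seed,
                               var_equal = TRUE, intensity = c("raw", "exceedance"),
                               n_rois, pairs) {
  intensity <- match.arg(intensity)
  S <- nrow(W)
  asgn <- perm_assignments(S, n_first, n_perm, seed)
  P <- length(asgn)
  G <- matrix(0, P, S)
  for (p in seq_len(P)) G[p, asgn[[p]]] <- 1
  n1 <- n_first
  n2 <- S - n1
  sum_all <- colSums(W)
  sumsq_all <- colSums(W * W)
  s1 <- G %*% W
  q1 <- G %*% (W * W)
  s2 <- rep(1, P) %o% sum_all - s1
  q2 <- rep(1, P) %o% sumsq_all - q1
  ss1 <- pmax(q1 - s1 * s1 / n1, 0)
  ss2 <- pmax(q2 - s2 * s2 / n2, 0)
  if (var_equal) {
    denom <- sqrt((ss1 + ss2) / (n1 + n2 - 2) * (1 / n1 + 1 / n2))
  } else {
    denom <- sqrt(ss1 / (n1 - 1) / n1 + ss2 / (n2 - 1) / n2)
  }
  tmat <- (s1 / n1 - s2 / n2) / denom
  tmat[denom == 0] <- -Inf
  null <- numeric(P)
  # the identity permutation recomputes the observed t-values along a different
  # floating-point path; a hair's tolerance keeps exact threshold ties intact
  tau_eff <- tau - 1e-9 * max(1, abs(tau))
  for (p in seq_len(P)) {
    tv <- tmat[p, ]
    keep <- which(is.finite(tv) & tv >= tau_eff)
    if (!length(keep)) {
      null[p] <- 0
      next
    }
    w <- if (intensity == "raw") tv[keep] else tv[keep] - tau
    null[p] <- max_component_intensity(pairs[keep, 1], pairs[keep, 2], w, n_rois)
  }
  attr(null, "exhaustive") <- attr(asgn, "exhaustive")
  null
}

observed_intensity <- function(net, intensity) {
  if (intensity == "raw") net$intensity else net$intensity - net$n_edges * net$threshold
}

#' Permutation familywise-error p-value for a dysconnected network
#'
#' Permutes the full label vector (group sizes preserved; exhaustive
#' enumeration is used automatically when the number of distinct assignments
#' is at most `n_perm`), recomputes the edgewise t-matrix under the same
#' contrast, thresholds at the same `tau`, and records the maximum component
#' intensity (0 when no edge survives). The p-value is the fraction of
#' permutations whose maximum intensity strictly exceeds the observed
#' component's intensity (`p_mode = "greater"`); `p_mode = "conservative"`
#' uses the add-one `(#{null >= obs} + 1) / (n + 1)` rule instead.
#'
#' @param cohort an [fn_cohort()].
#' @param labels optional label override (hypothesized labeling).
#' @param contrast `"ECP_GT_LCP"` or `"ECP_LT_LCP"`.
#' @param tau the threshold at which `observed` was produced.
#' @param observed a `dysconn` from this cohort/labeling at `tau`.
#' @param n_perm number of permutations (default 5000).
#' @param seed RNG seed for the permutation sampler.
#' @param var_equal pooled (default) vs Welch t.
#' @param intensity `"raw"` sums edge t-values (default); `"exceedance"` sums
#'   `t - tau`.
#' @param p_mode `"greater"` (default) or `"conservative"`.
#' @return The p-value in `[0, 1]`.
#' @export
permutation_pvalue <- function(cohort, labels = NULL, contrast = "ECP_GT_LCP",
                               tau, observed, n_perm = 5000, seed = 1,
                               var_equal = TRUE, intensity = c("raw", "exceedance"),
                               p_mode = c("greater", "conservative")) {
  stopifnot(inherits(cohort, "fn_cohort"), inherits(observed, "dysconn"))
  intensity <- match.arg(intensity)
  p_mode <- match.arg(p_mode)
  contrast <- check_contrast(contrast)
  labels <- if (is.null(labels)) cohort$label else as.character(labels)
  W <- cohort_edge_matrix(cohort)
  null <- null_max_intensity(
    W, sum(labels == favored_group(contrast)), tau, n_perm, seed,
    var_equal = var_equal, intensity = intensity,
    n_rois = cohort$n_rois, pairs = edge_pairs(cohort$n_rois)
  )
  pvalue_from_null(null, observed_intensity(observed, intensity), p_mode)
}

pvalue_from_null <- function(null, obs, p_mode = "greater") {
  # exact mathematical ties (notably the identity permutation reproducing the
  # observed statistic) must not flip on floating-point path differences:
  # "larger than" is taken beyond a small relative tolerance
  tol <- 1e-8 * max(1, abs(obs))
  if (p_mode == "greater") {
    mean(null > obs + tol)
  } else {
    (sum(null >= obs - tol) + 1) / (length(null) + 1)
  }
}

#' Select one dysconnected network from several candidates
#'
#' Smallest FWE p-value wins; ties go to the candidate with the most edges;
#' remaining ties are broken deterministically toward the component
#' containing the smallest ROI index.
#'
#' @param candidates list of `dysconn` objects, all with p-values set.
#' @return The selected `dysconn`, or the [no_component()] sentinel when
#'   `candidates` is empty.
#' @export
select_component <- function(candidates) {
  if (!length(candidates)) {
    return(no_component())
  }
  stopifnot(all(vapply(candidates, function(d) !is.na(d$p_value), logical(1))))
  p <- vapply(candidates, function(d) d$p_value, numeric(1))
  ne <- vapply(candidates, function(d) d$n_edges, numeric(1))
  mn <- vapply(candidates, function(d) min(d$nodes), numeric(1))
  candidates[[order(p, -ne, mn)[1]]]
}

#' Run the full NBS pipeline on a labeled cohort
#'
#' Composes the edgewise t-matrix, thresholding (at the percolation threshold
#' by default, or at a fixed value), per-candidate permutation FWE p-values
#' (one shared null distribution per threshold), and the selection rule.
#'
#' @param cohort an [fn_cohort()].
#' @param labels optional label override (hypothesized labeling).
#' @param contrast `"ECP_GT_LCP"` or `"ECP_LT_LCP"`.
#' @param threshold `"percolation"` (default) or a fixed numeric t-threshold.
#' @param n_perm,seed permutation settings (defaults 5000, 1).
#' @param var_equal,intensity,p_mode see [permutation_pvalue()].
#' @return An object of class `nbs_fit`: the selected `network` (a `dysconn`,
#'   possibly the no-component sentinel), all `candidates`, the `tstat`
#'   matrix, the threshold used, and the null distribution.
#' @export
run_nbs <- function(cohort, labels = NULL, contrast = "ECP_GT_LCP",
                    threshold = "percolation", n_perm = 5000, seed = 1,
                    var_equal = TRUE, intensity = c("raw", "exceedance"),
                    p_mode = c("greater", "conservative")) {
  stopifnot(inherits(cohort, "fn_cohort"))
  intensity <- match.arg(intensity)
  p_mode <- match.arg(p_mode)
  contrast <- check_contrast(contrast)
  labels <- if (is.null(labels)) cohort$label else as.character(labels)
  tmat <- edge_t_stats(cohort, labels, contrast, var_equal = var_equal)
  percolation_mode <- identical(threshold, "percolation")
  if (percolation_mode) {
    perc <- percolation_threshold(tmat)
    tau <- perc$threshold
    candidates <- list(perc$mcc)
  } else {
    stopifnot(is.numeric(threshold), length(threshold) == 1)
    tau <- threshold
    candidates <- suprathreshold_components(tmat, tau)
  }
  W <- cohort_edge_matrix(cohort)
  null <- NULL
  if (length(candidates)) {
    null <- null_max_intensity(
      W, sum(labels == favored_group(contrast)), tau, n_perm, seed,
      var_equal = var_equal, intensity = intensity,
      n_rois = cohort$n_rois, pairs = edge_pairs(cohort$n_rois)
    )
    candidates <- lapply(candidates, function(d) {
      d$p_value <- pvalue_from_null(null, observed_intensity(d, intensity), p_mode)
      d
    })
  }
  selected <- select_component(candidates)
  if (selected$no_component) {
    selected <- no_component(tau, cohort$n_rois)
  }
  structure(
    list(
      network = selected,
      candidates = candidates,
      tstat = tmat,
      threshold_mode = if (percolation_mode) "percolation" else "fixed",
      threshold = tau,
      contrast = contrast,
      n_perm = n_perm,
      seed = seed,
      null = null,
      intensity_mode = intensity,
      p_mode = p_mode
    ),
    class = "nbs_fit"
  )
}

#' @export
print.nbs_fit <- function(x, ...) {
  cat("NBS fit (contrast ", x$contrast, ", ", x$threshold_mode,
      " threshold t >= ", format(x$threshold, digits = 4), ", ",
      x$n_perm, " permutations)\n", sep = "")
  print(x$network)
  if (length(x$candidates) > 1) {
    cat("  (", length(x$candidates), " candidate components; smallest p selected)\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.nbs_fit <- function(object, ...) {
  net <- object$network
  out <- data.frame(
    contrast = object$contrast,
    threshold = object$threshold,
    n_edges = net$n_edges,
    n_nodes = length(net$nodes),
    intensity = net$intensity,
    p_value = net$p_value,
    n_perm = object$n_perm
  )
  class(out) <- c("summary.nbs_fit", class(out))
  out
}

#' @export
plot.nbs_fit <- function(x, ...) {
  net <- x$network
  if (isTRUE(net$no_component)) {
    stop("nothing to plot: no suprathreshold component")
  }
  g <- igraph::graph_from_edgelist(net$edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, net$n_rois - igraph::vcount(g)))
  igraph::E(g)$width <- 1 + 2 * (net$t_values - min(net$t_values)) /
    max(1e-9, diff(range(net$t_values)))
  plot(g, vertex.size = 6, vertex.label.cex = 0.6, ...)
  invisible(x)
}
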