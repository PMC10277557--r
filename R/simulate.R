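# Synthetic cohort generator: seeded cohorts with the statistical structure the
# pipeline assumes, including a planted subnetwork whose partial correlations
# differ between the two chronotype groups.

#' Specify a synthetic chronotype cohort
#'
#' Defaults emulate the study design the pipeline targets: 16 early (ECP) and
#' 22 late (LCP) circadian phenotype subjects, 70 ROIs, 450 timepoints per
#' scan, and a planted subnetwork of 30 edges whose partial correlation is
#' more positive in the ECP group by `effect_size` (so the detecting contrast
#' is ECP > LCP).
#'
#' @param n_ecp,n_lcp subjects per group (each must be >= 2 for t-tests).
#' @param n_rois number of ROIs N.
#' @param n_timepoints number of timepoints T per scan.
#' @param planted_edges two-column matrix of unordered 1-based ROI pairs, or
#'   `NULL` to sample `n_planted` distinct off-diagonal pairs from the seed.
#' @param n_planted number of planted edges when `planted_edges` is `NULL`.
#' @param effect_size dimensionless shift delta applied (as a subtraction) to
#'   the planted off-diagonal precision entries of the ECP group, making the
#'   planted partial correlations more positive for ECPs.
#' @param base_weight planted partial correlation shared by both groups before
#'   the effect is added (the LCP level).
#' @param subject_sd scale of the seeded per-subject symmetric perturbation of
#'   the precision matrix (between-subject heterogeneity).
#' @param noise_sd edge-level Gaussian noise scale used by
#'   [simulate_edge_cohort()].
#' @param ar1 lag-1 autocorrelation of the time-series innovations
#'   (stationary AR(1) with unit marginal variance); 0 disables temporal
#'   structure. The pipeline consumes only covariance, so this is a realism
#'   knob affecting effective sample size, not correctness.
#' @param seed RNG seed; all generation is reproducible given the spec.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_ecp = 16, n_lcp = 22, n_rois = 70, n_timepoints = 450,
                        planted_edges = NULL, n_planted = 30,
                        effect_size = 0.30, base_weight = 0.05,
                        subject_sd = 0.02, noise_sd = 0.1, ar1 = 0, seed = 1) {
  if (n_ecp < 2 || n_lcp < 2) {
    stop("each group needs at least 2 subjects (t-tests require >= 2 per group)")
  }
  stopifnot(n_rois >= 2, n_timepoints >= 2, abs(ar1) < 1, subject_sd >= 0, noise_sd >= 0)
  n_pairs <- n_rois * (n_rois - 1) / 2
  if (is.null(planted_edges)) {
    # sample a connected planted subnetwork (random spanning tree over
    # min(N, n_planted + 1) nodes plus extra within-subnetwork edges): the
    # planted effect then forms one subnetwork of the kind the minimum
    # connected component is designed to detect, not scattered edges
    n_planted <- min(n_planted, n_pairs)
    planted_edges <- with_seed(derive_seed(seed, 7919L), {
      k <- min(n_rois, n_planted + 1L)
      nodes <- sort(sample.int(n_rois, k))
      tree <- cbind(nodes[-1], vapply(2:k, function(v) nodes[sample.int(v - 1L, 1)], integer(1)))
      ij <- cbind(pmin(tree[, 1], tree[, 2]), pmax(tree[, 1], tree[, 2]))
      extra_pool <- edge_pairs(k)
      extra_pool <- cbind(nodes[extra_pool[, 1]], nodes[extra_pool[, 2]])
      in_tree <- paste(ij[, 1], ij[, 2]) # tree edges excluded from the extras
      pool <- extra_pool[!(paste(extra_pool[, 1], extra_pool[, 2]) %in% in_tree), , drop = FALSE]
      n_extra <- n_planted - nrow(ij)
      if (n_extra > 0) {
        ij <- rbind(ij, pool[sample.int(nrow(pool), n_extra), , drop = FALSE])
      }
      ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
    })
    storage.mode(planted_edges) <- "integer"
    colnames(planted_edges) <- c("i", "j")
  } else {
    planted_edges <- as.matrix(planted_edges)
    if (ncol(planted_edges) != 2) stop("planted_edges must be a two-column matrix of ROI pairs")
    storage.mode(planted_edges) <- "integer"
    ij <- cbind(pmin(planted_edges[, 1], planted_edges[, 2]),
                pmax(planted_edges[, 1], planted_edges[, 2]))
    if (any(ij[, 1] == ij[, 2]) || any(ij < 1) || any(ij > n_rois)) {
      stop("planted_edges must be off-diagonal pairs within 1..n_rois")
    }
    planted_edges <- unique(ij)
    colnames(planted_edges) <- c("i", "j")
  }
  structure(
    list(
      n_ecp = as.integer(n_ecp), n_lcp = as.integer(n_lcp),
      n_rois = as.integer(n_rois), n_timepoints = as.integer(n_timepoints),
      planted_edges = planted_edges,
      effect_size = effect_size, base_weight = base_weight,
      subject_sd = subject_sd, noise_sd = noise_sd, ar1 = ar1,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(
    "Synthetic cohort spec: ", x$n_ecp, " ECP + ", x$n_lcp, " LCP, ",
    x$n_rois, " ROIs x ", x$n_timepoints, " timepoints, ",
    nrow(x$planted_edges), " planted edges (delta = ", x$effect_size,
    ", base = ", x$base_weight, "), subject_sd = ", x$subject_sd,
    ", seed = ", x$seed, "\n",
    sep = ""
  )
  invisible(x)
}

# Diagonal loading in fixed increments until the minimum eigenvalue exceeds
# 1e-6; gives up after 100 increments. Returns the loaded matrix with the
# total loading recorded as an attribute.
load_to_pd <- function(omega, what = "precision matrix",
                       increment = 0.01, min_eig = 1e-6, max_steps = 100L) {
  total <- 0
  for (k in 0:max_steps) {
    ev <- min(eigen(omega, symmetric = TRUE, only.values = TRUE)$values)
    if (ev > min_eig) {
      attr(omega, "loading") <- total
      return(omega)
    }
    diag(omega) <- diag(omega) + increment
    total <- total + increment
  }
  stop("could not make ", what, " positive definite after ", max_steps,
       " diagonal-loading increments")
}

base_precision <- function(spec, group) {
  omega <- diag(spec$n_rois)
  w <- spec$base_weight + if (group == "ECP") spec$effect_size else 0
  pe <- spec$planted_edges
  omega[pe] <- omega[pe] - w
  omega[pe[, c(2, 1), drop = FALSE]] <- omega[pe]
  omega
}

# Sample T rows from N(0, Omega^-1) given precision Omega, with optional AR(1)
# innovations (stationary, unit marginal variance).
sample_gaussian_ts <- function(omega, t_len, ar1 = 0) {
  n <- nrow(omega)
  z <- matrix(stats::rnorm(t_len * n), t_len, n)
  if (ar1 != 0) {
    # x_1 = z_1, x_t = ar1 * x_{t-1} + sqrt(1 - ar1^2) * z_t: stationary,
    # unit marginal variance
    e <- z * sqrt(1 - ar1^2)
    e[1, ] <- z[1, ]
    z <- apply(e, 2, function(col) {
      as.numeric(stats::filter(col, ar1, method = "recursive"))
    })
  }
  u <- chol(omega)
  t(backsolve(u, t(z)))
}

#' Generate a synthetic ROI time-series cohort
#'
#' Each subject's series is T independent draws from a zero-mean multivariate
#' Gaussian whose precision matrix is a shared base (identity plus planted
#' couplings), with the planted entries shifted by `-effect_size` for ECP
#' subjects only (making planted partial correlations more positive for ECPs)
#' and a seeded per-subject symmetric perturbation of scale `subject_sd`.
#' Positive definiteness is restored by diagonal loading where needed, and
#' the loading applied is recorded in the result.
#'
#' @param spec a [cohort_spec()].
#' @return An object of class `roi_cohort` with attributes `planted_edges`,
#'   `effect_size`, `seed`, and `loading` (per-subject diagonal loading).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  labels <- c(rep("ECP", spec$n_ecp), rep("LCP", spec$n_lcp))
  ids <- sprintf("S%02d", seq_along(labels))
  bases <- list(ECP = base_precision(spec, "ECP"), LCP = base_precision(spec, "LCP"))
  loading <- numeric(length(labels))
  series <- with_seed(spec$seed, lapply(seq_along(labels), function(s) {
    omega <- bases[[labels[s]]]
    if (spec$subject_sd > 0) {
      n <- spec$n_rois
      noise <- matrix(stats::rnorm(n * n, sd = spec$subject_sd), n, n)
      noise <- (noise + t(noise)) / 2
      diag(noise) <- 0
      omega <- omega + noise
    }
    omega <- load_to_pd(omega, what = paste0("precision matrix for subject ", ids[s]))
    loading[s] <<- attr(omega, "loading")
    sample_gaussian_ts(omega, spec$n_timepoints, spec$ar1)
  }))
  out <- roi_cohort(series, ids, labels)
  attr(out, "planted_edges") <- spec$planted_edges
  attr(out, "effect_size") <- spec$effect_size
  attr(out, "seed") <- spec$seed
  attr(out, "loading") <- loading
  out
}

#' Generate a synthetic cohort of edge-weight networks directly
#'
#' Fast path bypassing time series: each subject's symmetric edge-weight
#' matrix is sampled as `base_weight` on planted edges (plus `effect_size`
#' for ECP subjects), 0 elsewhere, plus i.i.d. Gaussian edge noise of scale
#' `noise_sd`, clipped to `[-1, 1]`; the diagonal is `NA`.
#'
#' @param spec a [cohort_spec()].
#' @return An object of class `fn_cohort` with planted-edge attributes as in
#'   [simulate_cohort()].
#' @export
simulate_edge_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  labels <- c(rep("ECP", spec$n_ecp), rep("LCP", spec$n_lcp))
  ids <- sprintf("S%02d", seq_along(labels))
  n <- spec$n_rois
  pe <- spec$planted_edges
  mean_for <- function(group) {
    m <- matrix(0, n, n)
    w <- spec$base_weight + if (group == "ECP") spec$effect_size else 0
    m[pe] <- w
    m[pe[, c(2, 1), drop = FALSE]] <- w
    m
  }
  means <- list(ECP = mean_for("ECP"), LCP = mean_for("LCP"))
  nets <- with_seed(spec$seed, lapply(seq_along(labels), function(s) {
    noise <- matrix(stats::rnorm(n * n, sd = spec$noise_sd), n, n)
    noise[lower.tri(noise)] <- t(noise)[lower.tri(noise)]
    m <- means[[labels[s]]] + noise
    m <- pmin(pmax(m, -1), 1)
    diag(m) <- NA_real_
    m
  }))
  out <- fn_cohort(nets, ids, labels)
  attr(out, "planted_edges") <- spec$planted_edges
  attr(out, "effect_size") <- spec$effect_size
  attr(out, "seed") <- spec$seed
  out
}
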