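# The three-step four-network chronotype classifier for one held-out subject,
# plus the reduced shared-threshold variant.

#' Classifier configuration
#'
#' @param alpha significance threshold for the permutation FWE p-values
#'   (default 0.05); networks with `p < alpha` are significant.
#' @param mode `"percolation"` (per-labeling percolation thresholds) or a
#'   fixed numeric t-threshold shared by both labelings (the reduced
#'   classifier).
#' @param contrast `"ECP_GT_LCP"` or `"ECP_LT_LCP"`.
#' @param n_perm permutations per FWE p-value (default 5000).
#' @param seed base RNG seed; per-subject, per-network streams are derived
#'   from it so leave-one-out results are order-independent.
#' @param var_equal,intensity,p_mode see [permutation_pvalue()].
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(alpha = 0.05, mode = "percolation",
                              contrast = "ECP_GT_LCP", n_perm = 5000, seed = 1,
                              var_equal = TRUE, intensity = "raw",
                              p_mode = "greater") {
  stopifnot(alpha >= 0, alpha <= 1, n_perm >= 1)
  if (!identical(mode, "percolation")) {
    stopifnot(is.numeric(mode), length(mode) == 1, is.finite(mode))
  }
  structure(
    list(
      alpha = alpha, mode = mode, contrast = check_contrast(contrast),
      n_perm = as.integer(n_perm), seed = as.integer(seed),
      var_equal = var_equal, intensity = intensity, p_mode = p_mode
    ),
    class = "classifier_config"
  )
}

is_significant <- function(net, alpha) {
  !is.null(net) && !isTRUE(net$no_component) && !is.na(net$p_value) && net$p_value < alpha
}

# One NBS pass for a hypothesized labeling of subject m at a given threshold:
# candidates -> shared null -> per-candidate p -> selection.
nbs_pass <- function(W, labels, contrast, tau_spec, n_perm, seed, cfg, n_rois, pairs) {
  first <- labels == favored_group(cfg$contrast)
  tv <- edge_t_vector(W, first, var_equal = cfg$var_equal)
  if (identical(tau_spec, "percolation")) {
    perc <- percolation_threshold(edges_to_matrix(tv, n_rois))
    tau <- perc$threshold
    candidates <- list(perc$mcc)
  } else {
    tau <- tau_spec
    candidates <- suprathreshold_components(edges_to_matrix(tv, n_rois), tau)
  }
  if (!length(candidates)) {
    return(no_component(tau, n_rois))
  }
  null <- null_max_intensity(
    W, sum(first), tau, n_perm, seed,
    var_equal = cfg$var_equal, intensity = cfg$intensity,
    n_rois = n_rois, pairs = pairs
  )
  candidates <- lapply(candidates, function(d) {
    d$p_value <- pvalue_from_null(null, observed_intensity(d, cfg$intensity), cfg$p_mode)
    d
  })
  select_component(candidates)
}

#' Build the four dysconnected networks for one held-out subject
#'
#' With subject `m` hypothesized as ECP, the t-matrix over all subjects gives
#' the percolation threshold `t_E` and its minimum connected component
#' `E_tE`; likewise `t_L` and `L_tL` with `m` hypothesized as LCP. The cross
#' networks `E_tL` (m as ECP, threshold `t_L`) and `L_tE` (m as LCP,
#' threshold `t_E`) are only needed by step two of the classifier and are
#' materialized on request. In fixed-threshold mode `t_E = t_L = tau` and the
#' cross networks alias the direct ones.
#'
#' @param cohort an [fn_cohort()] containing subject `m`.
#' @param m subject index or subject id.
#' @param cfg a [classifier_config()].
#' @param materialize `"step1"` (default: only `E_tE`, `L_tL`) or `"all"`.
#' @return An object of class `network_quad`: `t_E`, `t_L`, `net_E_tE`,
#'   `net_L_tL`, `net_E_tL`, `net_L_tE` (the latter two `NULL` until
#'   materialized).
#' @export
build_quad <- function(cohort, m, cfg = classifier_config(), materialize = c("step1", "all")) {
  stopifnot(inherits(cohort, "fn_cohort"), inherits(cfg, "classifier_config"))
  materialize <- match.arg(materialize)
  if (is.character(m)) m <- match(m, cohort$subject_id)
  stopifnot(!is.na(m), m >= 1, m <= length(cohort$networks))
  others <- cohort$label[-m]
  if (sum(others == "ECP") < 2 || sum(others == "LCP") < 2) {
    stop("removing subject ", cohort$subject_id[m],
         " leaves fewer than 2 subjects in a group")
  }
  W <- cohort_edge_matrix(cohort)
  pairs <- edge_pairs(cohort$n_rois)
  labels_E <- replace(cohort$label, m, "ECP")
  labels_L <- replace(cohort$label, m, "LCP")
  seed_for <- function(k) derive_seed(cfg$seed, m * 8L + k)

  quad <- structure(
    list(
      subject_id = cohort$subject_id[m],
      subject_index = m,
      t_E = NA_real_, t_L = NA_real_,
      net_E_tE = NULL, net_L_tL = NULL, net_E_tL = NULL, net_L_tE = NULL,
      mode = if (identical(cfg$mode, "percolation")) "percolation" else "fixed",
      contrast = cfg$contrast
    ),
    class = "network_quad"
  )

  if (identical(cfg$mode, "percolation")) {
    net_E <- nbs_pass(W, labels_E, cfg$contrast, "percolation",
                      cfg$n_perm, seed_for(0L), cfg, cohort$n_rois, pairs)
    net_L <- nbs_pass(W, labels_L, cfg$contrast, "percolation",
                      cfg$n_perm, seed_for(1L), cfg, cohort$n_rois, pairs)
    quad$t_E <- net_E$threshold
    quad$t_L <- net_L$threshold
    net_E$label_context <- "E"
    net_L$label_context <- "L"
    net_E$subject_context <- net_L$subject_context <- cohort$subject_id[m]
    quad$net_E_tE <- net_E
    quad$net_L_tL <- net_L
    if (materialize == "all") {
      quad <- materialize_cross(quad, cohort, cfg, W, pairs, labels_E, labels_L, seed_for)
    }
  } else {
    tau <- cfg$mode
    net_E <- nbs_pass(W, labels_E, cfg$contrast, tau,
                      cfg$n_perm, seed_for(0L), cfg, cohort$n_rois, pairs)
    net_L <- nbs_pass(W, labels_L, cfg$contrast, tau,
                      cfg$n_perm, seed_for(1L), cfg, cohort$n_rois, pairs)
    quad$t_E <- quad$t_L <- tau
    net_E$label_context <- "E"
    net_L$label_context <- "L"
    net_E$subject_context <- net_L$subject_context <- cohort$subject_id[m]
    quad$net_E_tE <- net_E
    quad$net_L_tL <- net_L
    # shared threshold: the cross networks are literally the direct ones
    quad$net_E_tL <- net_E
    quad$net_L_tE <- net_L
  }
  quad
}

materialize_cross <- function(quad, cohort, cfg, W, pairs, labels_E, labels_L, seed_for) {
  if (is.null(quad$net_E_tL)) {
    net <- nbs_pass(W, labels_E, cfg$contrast, quad$t_L,
                    cfg$n_perm, seed_for(2L), cfg, cohort$n_rois, pairs)
    net$label_context <- "E"
    net$subject_context <- quad$subject_id
    quad$net_E_tL <- net
  }
  if (is.null(quad$net_L_tE)) {
    net <- nbs_pass(W, labels_L, cfg$contrast, quad$t_E,
                    cfg$n_perm, seed_for(3L), cfg, cohort$n_rois, pairs)
    net$label_context <- "L"
    net$subject_context <- quad$subject_id
    quad$net_L_tE <- net
  }
  quad
}

#' @export
print.network_quad <- function(x, ...) {
  fmt <- function(net, name) {
    if (is.null(net)) {
      cat("  ", name, ": not materialized\n", sep = "")
    } else if (isTRUE(net$no_component)) {
      cat("  ", name, ": no component\n", sep = "")
    } else {
      cat("  ", name, ": ", net$n_edges, " edges, p = ",
          format(net$p_value, digits = 4), "\n", sep = "")
    }
  }
  cat("Network quad for subject ", x$subject_id, " (", x$mode, " mode, contrast ",
      x$contrast, ")\n  t_E = ", format(x$t_E, digits = 4),
      ", t_L = ", format(x$t_L, digits = 4), "\n", sep = "")
  fmt(x$net_E_tE, "E_tE")
  fmt(x$net_L_tL, "L_tL")
  fmt(x$net_E_tL, "E_tL")
  fmt(x$net_L_tE, "L_tE")
  invisible(x)
}

#' Classifier step one: significance of the two direct networks
#'
#' If exactly one of `E_tE`, `L_tL` is significant (`p < alpha`), that
#' chronotype is the label; neither significant is `UNCLEAR`; both
#' significant defers to step two (`CONTINUE`).
#'
#' @param net_E_tE,net_L_tL `dysconn` objects with p-values set.
#' @param alpha significance threshold.
#' @return One of `"ECP"`, `"LCP"`, `"UNCLEAR"`, `"CONTINUE"`.
#' @export
classify_step1 <- function(net_E_tE, net_L_tL, alpha = 0.05) {
  sig_E <- is_significant(net_E_tE, alpha)
  sig_L <- is_significant(net_L_tL, alpha)
  if (sig_E && sig_L) "CONTINUE" else if (sig_E) "ECP" else if (sig_L) "LCP" else "UNCLEAR"
}

#' Classifier step two: significance of the two cross networks
#'
#' Same decision table as step one, applied to `E_tL` and `L_tE`.
#'
#' @param net_E_tL,net_L_tE `dysconn` objects with p-values set.
#' @param alpha significance threshold.
#' @return One of `"ECP"`, `"LCP"`, `"UNCLEAR"`, `"CONTINUE"`.
#' @export
classify_step2 <- function(net_E_tL, net_L_tE, alpha = 0.05) {
  classify_step1(net_E_tL, net_L_tE, alpha)
}

#' Classifier step three: edge-count comparison of the four networks
#'
#' Compares edge counts at matched thresholds: `|E_tE|` vs `|L_tE|` (both at
#' `t_E`) and `|E_tL|` vs `|L_tL|` (both at `t_L`). Both comparisons favoring
#' the same chronotype assigns that label; a conflict or any exact tie is
#' `UNCLEAR`. Correct labeling is assumed to sharpen the group separation, so
#' at a given threshold more edges survive under the true label.
#'
#' @param quad a fully materialized `network_quad` with all four networks
#'   significant.
#' @return One of `"ECP"`, `"LCP"`, `"UNCLEAR"`.
#' @export
classify_step3 <- function(quad) {
  a <- sign(quad$net_E_tE$n_edges - quad$net_L_tE$n_edges) # at t_E
  b <- sign(quad$net_E_tL$n_edges - quad$net_L_tL$n_edges) # at t_L
  if (a > 0 && b > 0) "ECP" else if (a < 0 && b < 0) "LCP" else "UNCLEAR"
}

# Pure decision function over a (sufficiently materialized) quad. Returns
# label + deciding step; `needs_cross = TRUE` signals that step 1 continued
# but the cross networks are absent.
classify_quad <- function(quad, alpha, mode = quad$mode) {
  if (mode == "fixed") {
    # reduced classifier: one significance check, then edge counts
    s1 <- classify_step1(quad$net_E_tE, quad$net_L_tL, alpha)
    if (s1 != "CONTINUE") {
      return(list(label = s1, step = 1L, needs_cross = FALSE))
    }
    d <- sign(quad$net_E_tE$n_edges - quad$net_L_tL$n_edges)
    label <- if (d > 0) "ECP" else if (d < 0) "LCP" else "UNCLEAR"
    return(list(label = label, step = if (label == "UNCLEAR") NA_integer_ else 3L,
                needs_cross = FALSE))
  }
  s1 <- classify_step1(quad$net_E_tE, quad$net_L_tL, alpha)
  if (s1 != "CONTINUE") {
    return(list(label = s1, step = 1L, needs_cross = FALSE))
  }
  if (is.null(quad$net_E_tL) || is.null(quad$net_L_tE)) {
    return(list(label = NA_character_, step = NA_integer_, needs_cross = TRUE))
  }
  s2 <- classify_step2(quad$net_E_tL, quad$net_L_tE, alpha)
  if (s2 != "CONTINUE") {
    return(list(label = s2, step = 2L, needs_cross = FALSE))
  }
  s3 <- classify_step3(quad)
  list(label = s3, step = if (s3 == "UNCLEAR") NA_integer_ else 3L, needs_cross = FALSE)
}

#' Classify one held-out subject
#'
#' Runs the three-step classifier in percolation mode (cross networks and
#' their permutation p-values are only materialized when step one is
#' inconclusive, since permutation testing dominates runtime), or the reduced
#' classifier in fixed-threshold mode. An `UNCLEAR` produced by the step-3
#' comparison (conflict or tie, i.e. the rules are exhausted) records no
#' deciding step.
#'
#' @param cohort an [fn_cohort()] containing the subject.
#' @param m subject index or id; its stored label is ignored during
#'   classification.
#' @param cfg a [classifier_config()].
#' @return An object of class `chrono_class`: `subject_id`, `assigned_label`
#'   in `ECP`/`LCP`/`UNCLEAR`, `deciding_step` (1, 2, 3 or `NA`), the `quad`,
#'   `alpha` and `contrast` used.
#' @export
classify_subject <- function(cohort, m, cfg = classifier_config()) {
  quad <- build_quad(cohort, m, cfg, materialize = "step1")
  res <- classify_quad(quad, cfg$alpha)
  if (isTRUE(res$needs_cross)) {
    W <- cohort_edge_matrix(cohort)
    pairs <- edge_pairs(cohort$n_rois)
    mi <- quad$subject_index
    labels_E <- replace(cohort$label, mi, "ECP")
    labels_L <- replace(cohort$label, mi, "LCP")
    seed_for <- function(k) derive_seed(cfg$seed, mi * 8L + k)
    quad <- materialize_cross(quad, cohort, cfg, W, pairs, labels_E, labels_L, seed_for)
    res <- classify_quad(quad, cfg$alpha)
  }
  structure(
    list(
      subject_id = quad$subject_id,
      assigned_label = res$label,
      deciding_step = res$step,
      quad = quad,
      alpha = cfg$alpha,
      contrast = cfg$contrast,
      mode = quad$mode
    ),
    class = "chrono_class"
  )
}

#' @export
print.chrono_class <- function(x, ...) {
  cat("Subject ", x$subject_id, ": ", x$assigned_label,
      if (!is.na(x$deciding_step)) paste0(" (step ", x$deciding_step, ")")
      else " (rules exhausted)",
      "  [", x$mode, " mode, contrast ", x$contrast, ", alpha = ", x$alpha, "]\n",
      sep = "")
  invisible(x)
}
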