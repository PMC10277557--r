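# Leave-one-out evaluation with the study's outcome metrics, t-threshold and
# significance-threshold sweeps, and leave-one-subject-out stability analysis.

#' Outcome metrics from true and assigned labels
#'
#' Accuracy is the fraction of all subjects classified correctly;
#' misclassification the fraction given a wrong definite label; unclear the
#' fraction abstained on. The three sum to 1 (an unclear outcome never counts
#' toward accuracy). Sensitivity is the fraction of true ECPs assigned ECP,
#' specificity the fraction of true LCPs assigned LCP, and balanced accuracy
#' their mean — reported because the group sizes are unbalanced.
#'
#' @param true_label character vector in `ECP`/`LCP`.
#' @param assigned_label character vector in `ECP`/`LCP`/`UNCLEAR`.
#' @param subject_id optional ids for the per-subject table.
#' @param deciding_step optional integer vector (1, 2, 3 or `NA`) recording
#'   which classifier step fired, tabulated per true group.
#' @return An object of class `chrono_eval`: fractions `accuracy`,
#'   `misclassification`, `unclear`, `sensitivity`, `specificity`,
#'   `balanced_accuracy`, a `per_subject` data.frame, and `step_counts`.
#' @export
evaluation_summary <- function(true_label, assigned_label, subject_id = NULL,
                               deciding_step = NULL) {
  n <- length(true_label)
  stopifnot(length(assigned_label) == n, n >= 1)
  stopifnot(all(true_label %in% c("ECP", "LCP")))
  stopifnot(all(assigned_label %in% c("ECP", "LCP", "UNCLEAR")))
  if (is.null(subject_id)) subject_id <- sprintf("S%02d", seq_len(n))
  if (is.null(deciding_step)) deciding_step <- rep(NA_integer_, n)

  correct <- assigned_label == true_label
  definite <- assigned_label != "UNCLEAR"
  n_ecp <- sum(true_label == "ECP")
  n_lcp <- sum(true_label == "LCP")
  sensitivity <- if (n_ecp > 0) sum(correct & true_label == "ECP") / n_ecp else NA_real_
  specificity <- if (n_lcp > 0) sum(correct & true_label == "LCP") / n_lcp else NA_real_

  step_fac <- factor(ifelse(is.na(deciding_step), "none", deciding_step),
                     levels = c("1", "2", "3", "none"))
  step_counts <- as.data.frame.matrix(
    table(true_label = factor(true_label, levels = c("ECP", "LCP")), step = step_fac)
  )

  structure(
    list(
      accuracy = mean(correct),
      misclassification = mean(definite & !correct),
      unclear = mean(!definite),
      sensitivity = sensitivity,
      specificity = specificity,
      balanced_accuracy = mean(c(sensitivity, specificity)),
      n_subjects = n,
      n_ecp = n_ecp,
      n_lcp = n_lcp,
      per_subject = data.frame(
        subject_id = subject_id,
        true_label = true_label,
        assigned_label = assigned_label,
        deciding_step = deciding_step,
        stringsAsFactors = FALSE
      ),
      step_counts = step_counts
    ),
    class = "chrono_eval"
  )
}

#' @export
print.chrono_eval <- function(x, ...) {
  pc <- function(v) sprintf("%.1f%%", 100 * v)
  cat("Chronotype classification over ", x$n_subjects, " subjects (",
      x$n_ecp, " ECP / ", x$n_lcp, " LCP)\n",
      "  accuracy ", pc(x$accuracy),
      " | misclassified ", pc(x$misclassification),
      " | unclear ", pc(x$unclear), "\n",
      "  sensitivity ", pc(x$sensitivity),
      " | specificity ", pc(x$specificity),
      " | balanced ", pc(x$balanced_accuracy), "\n",
      sep = "")
  invisible(x)
}

#' @export
summary.chrono_eval <- function(object, ...) {
  print(object)
  cat("  subjects deciding at each step (columns) by true group:\n")
  print(object$step_counts)
  invisible(object)
}

#' Leave-one-out evaluation of the chronotype classifier
#'
#' Classifies every subject with the remaining subjects as the training set
#' (the held-out subject is hypothesized as ECP and then LCP inside the NBS
#' pipeline) and summarizes outcomes with [evaluation_summary()].
#'
#' @param cohort an [fn_cohort()] with at least 3 subjects per group (so each
#'   leave-one-out fold retains at least 2).
#' @param cfg a [classifier_config()].
#' @return A `chrono_eval` with per-subject assignments and step counts.
#' @export
evaluate_loo <- function(cohort, cfg = classifier_config()) {
  stopifnot(inherits(cohort, "fn_cohort"))
  if (sum(cohort$label == "ECP") < 3 || sum(cohort$label == "LCP") < 3) {
    stop("leave-one-out evaluation needs at least 3 subjects per group")
  }
  res <- lapply(seq_along(cohort$networks), function(m) classify_subject(cohort, m, cfg))
  evaluation_summary(
    true_label = cohort$label,
    assigned_label = vapply(res, function(r) r$assigned_label, character(1)),
    subject_id = cohort$subject_id,
    deciding_step = vapply(res, function(r) r$deciding_step, integer(1))
  )
}

sweep_summary_row <- function(value, ev) {
  data.frame(
    value = value,
    accuracy = ev$accuracy,
    misclassification = ev$misclassification,
    unclear = ev$unclear,
    sensitivity = ev$sensitivity,
    specificity = ev$specificity,
    balanced_accuracy = ev$balanced_accuracy
  )
}

#' Sweep the shared t-statistic threshold
#'
#' Runs the reduced (shared-threshold) classifier in a leave-one-out loop at
#' every threshold of the grid. Per subject and hypothesized labeling, the
#' observed t-vector and the permutation-null t-matrices are computed once
#' and re-thresholded at each grid value. Also reports the percolation
#' threshold of the correctly-labeled cohort for reference. No
#' multiple-comparison correction is applied across the grid; the sweep is
#' exploratory.
#'
#' @param cohort an [fn_cohort()].
#' @param contrast `"ECP_GT_LCP"` or `"ECP_LT_LCP"`.
#' @param alpha significance threshold (default 0.05).
#' @param grid increasing threshold grid (default `seq(0, 4.5, by = 0.01)`).
#' @param n_perm,seed,var_equal,intensity,p_mode see [classifier_config()].
#' @return An object of class `sweep_result` with one summary row per grid
#'   value, the per-value `chrono_eval`s, and `percolation_true`.
#' @export
sweep_threshold <- function(cohort, contrast = "ECP_GT_LCP", alpha = 0.05,
                            grid = seq(0, 4.5, by = 0.01), n_perm = 5000,
                            seed = 1, var_equal = TRUE, intensity = "raw",
                            p_mode = "greater") {
  stopifnot(inherits(cohort, "fn_cohort"))
  stopifnot(is.numeric(grid), length(grid) >= 1, !is.unsorted(grid, strictly = TRUE))
  contrast <- check_contrast(contrast)
  if (sum(cohort$label == "ECP") < 3 || sum(cohort$label == "LCP") < 3) {
    stop("threshold sweep needs at least 3 subjects per group")
  }
  W <- cohort_edge_matrix(cohort)
  S <- length(cohort$networks)
  n_rois <- cohort$n_rois
  pairs <- edge_pairs(n_rois)

  # percolation threshold under the true labeling (reference line)
  perc_true <- percolation_threshold(
    edge_t_stats(cohort, contrast = contrast, var_equal = var_equal)
  )$threshold

  # per (subject, labeling): observed t-vector and cached permutation tapestry
  prep <- lapply(seq_len(S), function(m) {
    lapply(c(E = "ECP", L = "LCP"), function(hyp) {
      labels <- replace(cohort$label, m, hyp)
      first <- labels == favored_group(contrast)
      k <- if (hyp == "ECP") 0L else 1L
      list(
        tv = edge_t_vector(W, first, var_equal = var_equal),
        n_first = sum(first),
        seed = derive_seed(seed, m * 8L + k)
      )
    })
  })

  fixed_pass <- function(pr, tau) {
    candidates <- suprathreshold_components(edges_to_matrix(pr$tv, n_rois), tau)
    if (!length(candidates)) {
      return(no_component(tau, n_rois))
    }
    null <- null_max_intensity(
      W, pr$n_first, tau, n_perm, pr$seed,
      var_equal = var_equal, intensity = intensity,
      n_rois = n_rois, pairs = pairs
    )
    candidates <- lapply(candidates, function(d) {
      d$p_value <- pvalue_from_null(null, observed_intensity(d, intensity), p_mode)
      d
    })
    select_component(candidates)
  }

  evals <- vector("list", length(grid))
  for (g in seq_along(grid)) {
    tau <- grid[g]
    assigned <- character(S)
    steps <- rep(NA_integer_, S)
    for (m in seq_len(S)) {
      net_E <- fixed_pass(prep[[m]]$E, tau)
      net_L <- fixed_pass(prep[[m]]$L, tau)
      quad <- structure(
        list(
          subject_id = cohort$subject_id[m], subject_index = m,
          t_E = tau, t_L = tau,
          net_E_tE = net_E, net_L_tL = net_L,
          net_E_tL = net_E, net_L_tE = net_L,
          mode = "fixed", contrast = contrast
        ),
        class = "network_quad"
      )
      dec <- classify_quad(quad, alpha, mode = "fixed")
      assigned[m] <- dec$label
      steps[m] <- dec$step
    }
    evals[[g]] <- evaluation_summary(cohort$label, assigned, cohort$subject_id, steps)
  }

  structure(
    list(
      parameter = "t_threshold",
      grid = grid,
      table = do.call(rbind, Map(sweep_summary_row, grid, evals)),
      evaluations = evals,
      percolation_true = perc_true,
      contrast = contrast,
      alpha = alpha
    ),
    class = "sweep_result"
  )
}

#' Sweep the significance threshold
#'
#' Materializes every subject's full network quad (all four permutation
#' p-values) once — p-values do not depend on alpha — then re-runs the
#' decision rules at each alpha of the grid. At `alpha = 0` nothing is
#' significant, so every classification is unclear; once alpha exceeds every
#' subject's four p-values the outcome no longer changes, so accuracy
#' plateaus.
#'
#' @param cohort an [fn_cohort()].
#' @param cfg a [classifier_config()] (its `alpha` is ignored; the grid
#'   supplies it).
#' @param grid increasing alpha grid in `[0, 1]` (default
#'   `seq(0, 1, by = 0.01)`).
#' @return A `sweep_result` with one summary row per alpha.
#' @export
sweep_alpha <- function(cohort, cfg = classifier_config(), grid = seq(0, 1, by = 0.01)) {
  stopifnot(inherits(cohort, "fn_cohort"), inherits(cfg, "classifier_config"))
  stopifnot(is.numeric(grid), all(grid >= 0), all(grid <= 1),
            !is.unsorted(grid, strictly = TRUE))
  if (sum(cohort$label == "ECP") < 3 || sum(cohort$label == "LCP") < 3) {
    stop("alpha sweep needs at least 3 subjects per group")
  }
  quads <- lapply(seq_along(cohort$networks), function(m) {
    build_quad(cohort, m, cfg, materialize = "all")
  })
  evals <- lapply(grid, function(a) {
    dec <- lapply(quads, classify_quad, alpha = a)
    evaluation_summary(
      cohort$label,
      vapply(dec, function(d) d$label, character(1)),
      cohort$subject_id,
      vapply(dec, function(d) d$step, integer(1))
    )
  })
  structure(
    list(
      parameter = "alpha",
      grid = grid,
      table = do.call(rbind, Map(sweep_summary_row, grid, evals)),
      evaluations = evals,
      quads = quads,
      contrast = cfg$contrast,
      mode = if (identical(cfg$mode, "percolation")) "percolation" else "fixed"
    ),
    class = "sweep_result"
  )
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("Sweep over ", x$parameter, " (", length(x$grid), " grid values, contrast ",
      x$contrast, ")\n", sep = "")
  best <- x$table[which.max(x$table$accuracy), , drop = FALSE]
  cat("  best accuracy ", sprintf("%.1f%%", 100 * best$accuracy),
      " at ", x$parameter, " = ", format(best$value, digits = 4), "\n", sep = "")
  if (!is.null(x$percolation_true)) {
    cat("  percolation threshold under true labels: ",
        format(x$percolation_true, digits = 4), "\n", sep = "")
  }
  invisible(x)
}

#' @export
plot.sweep_result <- function(x, ...) {
  frac <- t(as.matrix(x$table[, c("accuracy", "misclassification", "unclear")]))
  graphics::barplot(frac, names.arg = format(x$grid, digits = 3),
                    col = c("steelblue", "firebrick", "goldenrod"),
                    border = NA, space = 0,
                    xlab = x$parameter, ylab = "fraction of subjects", ...)
  graphics::legend("topright", legend = c("correct", "incorrect", "unclear"),
                   fill = c("steelblue", "firebrick", "goldenrod"), bty = "n")
  if (!is.null(x$percolation_true)) {
    pos <- stats::approx(x$grid, seq_along(x$grid), xout = x$percolation_true)$y
    if (!is.na(pos)) graphics::abline(v = pos, lty = 2)
  }
  invisible(x)
}

#' Leave-one-subject-out stability analysis
#'
#' Removes each subject in turn (from both training and test sets) and runs a
#' full leave-one-out evaluation on the remaining N - 1 subjects. Consistent
#' rows indicate a classifier that is not overly dependent on any single
#' subject.
#'
#' @param cohort an [fn_cohort()] with at least 4 subjects per group.
#' @param cfg a [classifier_config()].
#' @return An object of class `stability_table`: one row per removed subject
#'   (accuracy, unclear, misclassification, balanced accuracy), column means,
#'   and the per-row `chrono_eval`s.
#' @export
stability_analysis <- function(cohort, cfg = classifier_config()) {
  stopifnot(inherits(cohort, "fn_cohort"))
  if (sum(cohort$label == "ECP") < 4 || sum(cohort$label == "LCP") < 4) {
    stop("stability analysis needs at least 4 subjects per group")
  }
  S <- length(cohort$networks)
  evals <- lapply(seq_len(S), function(r) evaluate_loo(cohort[-r], cfg))
  tab <- data.frame(
    removed_subject = cohort$subject_id,
    accuracy = vapply(evals, function(e) e$accuracy, numeric(1)),
    unclear = vapply(evals, function(e) e$unclear, numeric(1)),
    misclassification = vapply(evals, function(e) e$misclassification, numeric(1)),
    balanced_accuracy = vapply(evals, function(e) e$balanced_accuracy, numeric(1)),
    stringsAsFactors = FALSE
  )
  structure(
    list(table = tab, means = colMeans(tab[, -1]), evaluations = evals),
    class = "stability_table"
  )
}

#' @export
print.stability_table <- function(x, ...) {
  cat("Leave-one-subject-out stability over ", nrow(x$table), " removals\n", sep = "")
  cat("  mean accuracy ", sprintf("%.3f", x$means["accuracy"]),
      " | unclear ", sprintf("%.3f", x$means["unclear"]),
      " | misclassified ", sprintf("%.3f", x$means["misclassification"]), "\n",
      sep = "")
  invisible(x)
}

#' Percentage of definite (non-abstained) classifications
#'
#' `100 * #(ECP or LCP) / #(non-NA entries)`, rounded to one decimal place
#' (the convention used in per-session label tables, where `NA` marks an
#' excluded scan).
#'
#' @param labels character vector over `ECP`, `LCP`, `UNC`/`UNCLEAR`, `NA`.
#' @return Percentage (one decimal place).
#' @export
percent_definite <- function(labels) {
  valid <- !is.na(labels)
  if (!any(valid)) stop("all entries are NA")
  round(100 * sum(labels[valid] %in% c("ECP", "LCP")) / sum(valid), 1)
}

#' Degree summary of a dysconnected network over the full parcellation
#'
#' Degrees are computed over all `n_total` parcellation nodes, counting
#' untouched nodes as degree 0, so the mean degree is `2 * n_edges /
#' n_total`. The standard deviation uses the population (divide-by-N)
#' convention.
#'
#' @param net a `dysconn`.
#' @param n_total parcellation size (defaults to the network's own `n_rois`).
#' @return List with `mean_degree`, `sd_degree`, `max_degree`, `max_nodes`
#'   (all nodes attaining the maximum), and the full `degrees` vector.
#' @export
network_degree_summary <- function(net, n_total = net$n_rois) {
  stopifnot(inherits(net, "dysconn"), is.finite(n_total),
            n_total >= length(net$nodes))
  deg <- integer(n_total)
  if (net$n_edges > 0) {
    tab <- table(factor(as.integer(net$edges), levels = seq_len(n_total)))
    deg <- as.integer(tab)
  }
  mean_deg <- 2 * net$n_edges / n_total
  list(
    mean_degree = mean_deg,
    sd_degree = sqrt(mean((deg - mean_deg)^2)),
    max_degree = max(deg),
    max_nodes = which(deg == max(deg)),
    degrees = deg
  )
}
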