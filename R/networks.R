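# Functional-network construction: Tikhonov-regularized partial correlation
# from ROI time series, and the cohort-level lambda optimization objective.

#' Standardize ROI time series columnwise
#'
#' Centers each ROI's series to mean 0 and scales to sample standard
#' deviation 1 (divisor T - 1).
#'
#' @param series numeric T x N matrix (rows = timepoints, columns = ROIs).
#' @return The standardized T x N matrix.
#' @export
standardize_series <- function(series) {
  series <- as.matrix(series)
  sds <- apply(series, 2, stats::sd)
  zero <- which(sds == 0 | !is.finite(sds))
  if (length(zero)) {
    stop("zero-variance ROI column(s): ", paste(zero, collapse = ", "))
  }
  scale(series, center = TRUE, scale = sds)[, , drop = FALSE]
}

#' Tikhonov-regularized precision matrix
#'
#' Inverts the covariance matrix after ridge regularization:
#' `(cov + lambda * I)^-1`. The regularization makes the inverse well defined
#' even when T < N.
#'
#' @param cov symmetric N x N covariance matrix.
#' @param lambda nonnegative regularization parameter.
#' @return The symmetric N x N precision matrix.
#' @export
tikhonov_precision <- function(cov, lambda) {
  stopifnot(lambda >= 0)
  n <- nrow(cov)
  reg <- cov + diag(lambda, n)
  p <- tryCatch(
    solve(reg),
    error = function(e) {
      stop("covariance + lambda * I is singular (lambda = ", lambda,
           "); try a larger lambda", call. = FALSE)
    }
  )
  (p + t(p)) / 2
}

#' Partial correlations from a precision matrix
#'
#' `rho_ij = -p_ij / sqrt(p_ii * p_jj)` for i != j. Self-links are not
#' interpretable under partial correlation, so the diagonal is set to `NA`.
#'
#' @param precision symmetric N x N precision matrix with strictly positive
#'   diagonal.
#' @return N x N matrix of partial correlations in `[-1, 1]`, `NA` diagonal.
#' @export
partial_correlation <- function(precision) {
  d <- diag(precision)
  if (any(d <= 0)) {
    stop("precision matrix has non-positive diagonal entries: ",
         paste(which(d <= 0), collapse = ", "))
  }
  s <- 1 / sqrt(d)
  rho <- -(precision * outer(s, s))
  rho <- pmin(pmax(rho, -1), 1) # clip numerical overshoot beyond +/- 1
  diag(rho) <- NA_real_
  rho
}

#' Build one subject's functional network
#'
#' Full chain: standardize, sample covariance (equal to the correlation
#' matrix after standardization), Tikhonov precision, partial correlation.
#'
#' @param series numeric T x N matrix of ROI time series.
#' @param lambda Tikhonov regularization parameter.
#' @return Symmetric N x N partial-correlation matrix with `NA` diagonal.
#' @export
build_network <- function(series, lambda) {
  z <- standardize_series(series)
  partial_correlation(tikhonov_precision(stats::cov(z), lambda))
}

#' Build functional networks for a whole cohort
#'
#' @param cohort an [roi_cohort()].
#' @param lambda Tikhonov regularization parameter (a single value shared by
#'   all subjects; see [optimize_lambda()]).
#' @return An [fn_cohort()] of partial-correlation networks.
#' @export
build_networks <- function(cohort, lambda) {
  stopifnot(inherits(cohort, "roi_cohort"))
  nets <- lapply(cohort$series, build_network, lambda = lambda)
  out <- fn_cohort(nets, cohort$subject_id, cohort$label)
  attr(out, "lambda") <- lambda
  out
}

subject_precisions <- function(covs, lambda) {
  lapply(covs, function(cv) tikhonov_precision(cv, lambda))
}

lambda_objective_value <- function(covs, lambda) {
  ps <- subject_precisions(covs, lambda)
  n <- nrow(ps[[1]])
  ut <- upper.tri(matrix(0, n, n))
  pbar <- Reduce(`+`, ps) / length(ps)
  sq <- 0
  for (p in ps) {
    d <- (pbar - p)[ut]
    sq <- sq + sum(d * d)
  }
  sqrt(sq)
}

#' Optimize the Tikhonov regularization parameter over a cohort
#'
#' For each candidate lambda, computes every subject's Tikhonov precision
#' matrix and the cohort-average precision matrix, then the objective
#' `F(lambda) = sqrt( sum_{i<j} sum_m ( Pbar_ij - P^m_ij )^2 )` over the
#' off-diagonal upper triangle. The optimum is the grid value minimizing F
#' (ties broken toward the smallest lambda). When multiple cohorts (e.g.
#' scanning sessions) are supplied, a single global lambda is fitted on the
#' pooled subjects.
#'
#' By default a coarse 200-point logarithmic grid on `[1e-4, 10]` is searched
#' and then refined once with a 100-point linear grid around the coarse
#' minimizer.
#'
#' @param cohort an [roi_cohort()], or a list of them.
#' @param grid optional increasing vector of nonnegative candidate lambdas;
#'   `NULL` uses the default two-stage grid.
#' @return An object of class `lambda_opt`: list with `lambda` (the optimum),
#'   `curve` (data.frame of lambda, objective), and `invalid` (grid values
#'   excluded because some subject's regularized covariance was singular).
#' @export
optimize_lambda <- function(cohort, grid = NULL) {
  if (inherits(cohort, "roi_cohort")) cohort <- list(cohort)
  stopifnot(all(vapply(cohort, inherits, logical(1), "roi_cohort")))
  covs <- unlist(lapply(cohort, function(co) {
    lapply(co$series, function(s) stats::cov(standardize_series(s)))
  }), recursive = FALSE)
  if (length(covs) < 2) stop("lambda optimization needs at least 2 subjects")

  eval_grid <- function(grid) {
    vals <- rep(NA_real_, length(grid))
    for (k in seq_along(grid)) {
      vals[k] <- tryCatch(lambda_objective_value(covs, grid[k]), error = function(e) NA_real_)
    }
    vals
  }

  if (is.null(grid)) {
    coarse <- 10^seq(log10(1e-4), log10(10), length.out = 200)
    f_coarse <- eval_grid(coarse)
    ok <- which(!is.na(f_coarse))
    if (!length(ok)) stop("no valid lambda on the default grid")
    kmin <- ok[which.min(f_coarse[ok])]
    lo <- if (kmin > 1) coarse[kmin - 1] else coarse[1]
    hi <- if (kmin < length(coarse)) coarse[kmin + 1] else coarse[length(coarse)]
    fine <- seq(lo, hi, length.out = 100)
    f_fine <- eval_grid(fine)
    lambda_all <- c(coarse, fine)
    f_all <- c(f_coarse, f_fine)
  } else {
    stopifnot(is.numeric(grid), length(grid) >= 1, all(grid >= 0), !is.unsorted(grid, strictly = TRUE))
    lambda_all <- grid
    f_all <- eval_grid(grid)
  }

  ord <- order(lambda_all)
  lambda_all <- lambda_all[ord]
  f_all <- f_all[ord]
  dup <- duplicated(lambda_all)
  lambda_all <- lambda_all[!dup]
  f_all <- f_all[!dup]
  invalid <- lambda_all[is.na(f_all)]
  if (length(invalid)) {
    warning("excluded ", length(invalid), " lambda value(s) with singular regularized covariance")
  }
  valid <- which(!is.na(f_all))
  if (!length(valid)) stop("no valid lambda in the supplied grid")
  # ties -> smallest lambda (grid is sorted; which.min takes the first)
  best <- valid[which.min(f_all[valid])]
  structure(
    list(
      lambda = lambda_all[best],
      objective = f_all[best],
      curve = data.frame(lambda = lambda_all, objective = f_all),
      invalid = invalid,
      n_subjects = length(covs)
    ),
    class = "lambda_opt"
  )
}

#' @export
print.lambda_opt <- function(x, ...) {
  cat("Tikhonov lambda optimization over ", x$n_subjects, " subjects\n",
      "  optimal lambda = ", format(x$lambda, digits = 4),
      "  (objective = ", format(x$objective, digits = 6), ")\n",
      sep = "")
  if (length(x$invalid)) {
    cat("  excluded ", length(x$invalid), " singular grid value(s)\n", sep = "")
  }
  invisible(x)
}

#' @export
plot.lambda_opt <- function(x, ...) {
  ok <- !is.na(x$curve$objective)
  plot(x$curve$lambda[ok], x$curve$objective[ok],
       log = "x", type = "l",
       xlab = expression(lambda), ylab = "objective F",
       main = "Tikhonov regularization objective", ...)
  graphics::abline(v = x$lambda, lty = 2, col = "red")
  invisible(x)
}
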