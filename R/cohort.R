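# Cohort containers: ROI time-series cohorts and functional-network cohorts.

VALID_LABELS <- c("ECP", "LCP", "UNKNOWN")

#' Construct an ROI time-series cohort
#'
#' Bundles per-subject ROI time series (rows = timepoints, columns = ROIs)
#' with chronotype labels. All subjects must share the same number of ROIs;
#' the number of timepoints may vary. `T >= N` is not required: rank
#' deficiency is handled downstream by Tikhonov regularization.
#'
#' @param series list of numeric T x N matrices, one per subject.
#' @param subject_id character vector of unique subject identifiers.
#' @param label character vector of labels in `ECP`, `LCP`, `UNKNOWN`.
#' @return An object of class `roi_cohort`.
#' @export
roi_cohort <- function(series, subject_id, label) {
  stopifnot(is.list(series), length(series) >= 1L)
  if (length(subject_id) != length(series) || length(label) != length(series)) {
    stop("series, subject_id and label must have the same length")
  }
  if (anyDuplicated(subject_id)) {
    stop(
      "duplicate subject id: ",
      paste(unique(subject_id[duplicated(subject_id)]), collapse = ", ")
    )
  }
  bad <- setdiff(unique(label), VALID_LABELS)
  if (length(bad)) {
    stop("unknown label token: ", paste(bad, collapse = ", "))
  }
  n_rois <- unique(vapply(series, ncol, integer(1)))
  if (length(n_rois) != 1L) {
    stop("dimension mismatch: subjects disagree on the number of ROIs (", paste(n_rois, collapse = ", "), ")")
  }
  if (any(vapply(series, function(m) anyNA(m) || any(!is.finite(m)), logical(1)))) {
    stop("time series contain missing or non-finite values")
  }
  structure(
    list(
      series = series,
      subject_id = as.character(subject_id),
      label = as.character(label),
      n_rois = n_rois
    ),
    class = "roi_cohort"
  )
}

#' @export
print.roi_cohort <- function(x, ...) {
  tp <- range(vapply(x$series, nrow, integer(1)))
  cat(
    "ROI time-series cohort: ", length(x$series), " subjects (",
    sum(x$label == "ECP"), " ECP / ", sum(x$label == "LCP"), " LCP), ",
    x$n_rois, " ROIs, ",
    if (tp[1] == tp[2]) paste0(tp[1], " timepoints") else paste0(tp[1], "-", tp[2], " timepoints"),
    "\n",
    sep = ""
  )
  invisible(x)
}

#' Construct a functional-network cohort
#'
#' Bundles per-subject symmetric weighted adjacency matrices (partial
#' correlations in `[-1, 1]`, `NA` diagonal) with chronotype labels. The
#' diagonal is not interpretable under partial correlation and is stored as
#' `NA`.
#'
#' @param networks list of symmetric N x N numeric matrices.
#' @param subject_id character vector of unique subject identifiers.
#' @param label character vector of labels in `ECP`, `LCP`, `UNKNOWN`.
#' @return An object of class `fn_cohort`.
#' @export
fn_cohort <- function(networks, subject_id, label) {
  stopifnot(is.list(networks), length(networks) >= 1L)
  if (length(subject_id) != length(networks) || length(label) != length(networks)) {
    stop("networks, subject_id and label must have the same length")
  }
  if (anyDuplicated(subject_id)) {
    stop(
      "duplicate subject id: ",
      paste(unique(subject_id[duplicated(subject_id)]), collapse = ", ")
    )
  }
  bad <- setdiff(unique(label), VALID_LABELS)
  if (length(bad)) {
    stop("unknown label token: ", paste(bad, collapse = ", "))
  }
  n <- unique(vapply(networks, nrow, integer(1)))
  if (length(n) != 1L || any(vapply(networks, ncol, integer(1)) != n)) {
    stop("dimension mismatch: networks are not all square matrices of equal size")
  }
  networks <- lapply(seq_along(networks), function(s) {
    m <- networks[[s]]
    off <- m[upper.tri(m)]
    lo <- t(m)[upper.tri(m)]
    if (max(abs(off - lo), na.rm = TRUE) > 1e-8) {
      stop("network for subject ", subject_id[s], " is not symmetric (tolerance 1e-8)")
    }
    if (any(abs(off) > 1 + 1e-10, na.rm = TRUE)) {
      stop("network for subject ", subject_id[s], " has edge weights outside [-1, 1]")
    }
    m <- (m + t(m)) / 2
    diag(m) <- NA_real_
    m
  })
  structure(
    list(
      networks = networks,
      subject_id = as.character(subject_id),
      label = as.character(label),
      n_rois = n
    ),
    class = "fn_cohort"
  )
}

#' @export
print.fn_cohort <- function(x, ...) {
  cat(
    "Functional-network cohort: ", length(x$networks), " subjects (",
    sum(x$label == "ECP"), " ECP / ", sum(x$label == "LCP"), " LCP), ",
    x$n_rois, " x ", x$n_rois, " partial-correlation networks\n",
    sep = ""
  )
  invisible(x)
}

#' Subset a functional-network cohort by subject index
#' @param x an `fn_cohort`.
#' @param i integer or logical index over subjects.
#' @param ... unused.
#' @export
`[.fn_cohort` <- function(x, i, ...) {
  fn_cohort(x$networks[i], x$subject_id[i], x$label[i])
}

#' @noRd
cohort_edge_matrix <- function(cohort) {
  edge_matrix(cohort$networks)
}
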