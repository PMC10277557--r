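# Readers and writers: delimited time-series and adjacency matrices, label
# and ROI-metadata tables, edge lists, JSON summaries, and BrainNet Viewer
# .node/.edge exports. ROI indices are 1-based in all external files.

#' Write a cohort to disk
#'
#' Time-series cohorts get one tab-delimited file per subject (T rows x N
#' columns, header = 1-based ROI indices); network cohorts get one N x N
#' matrix file per subject (NaN diagonal). A `labels.tsv` (subject_id, label)
#' is always written, and synthetic cohorts also get a `ground_truth.json`
#' (planted edges, effect size, seed).
#'
#' @param cohort an [roi_cohort()] or [fn_cohort()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  is_ts <- inherits(cohort, "roi_cohort")
  stopifnot(is_ts || inherits(cohort, "fn_cohort"))
  items <- if (is_ts) cohort$series else cohort$networks
  files <- character(0)
  for (s in seq_along(items)) {
    path <- file.path(dir, paste0(cohort$subject_id[s], ".tsv"))
    m <- items[[s]]
    colnames(m) <- as.character(seq_len(ncol(m)))
    utils::write.table(format(m, digits = 15, trim = TRUE), path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, path)
  }
  lab_path <- file.path(dir, "labels.tsv")
  utils::write.table(
    data.frame(subject_id = cohort$subject_id, label = cohort$label),
    lab_path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  files <- c(files, lab_path)
  if (!is.null(attr(cohort, "planted_edges"))) {
    gt_path <- file.path(dir, "ground_truth.json")
    pe <- attr(cohort, "planted_edges")
    write_summary_json(
      list(
        planted_edges = unname(apply(pe, 1, function(r) as.list(r), simplify = FALSE)),
        effect_size = attr(cohort, "effect_size"),
        seed = attr(cohort, "seed")
      ),
      gt_path
    )
    files <- c(files, gt_path)
  }
  invisible(files)
}

#' Read a labels table
#'
#' @param path tab-delimited file with columns `subject_id`, `label`.
#' @return data.frame with character columns.
#' @export
read_labels <- function(path) {
  lab <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("subject_id", "label") %in% names(lab))) {
    stop("labels file ", path, " must have columns subject_id and label")
  }
  lab
}

match_labels <- function(ids, labels_df, source) {
  idx <- match(ids, labels_df$subject_id)
  if (anyNA(idx)) {
    stop("labels file does not cover subject id(s): ",
         paste(ids[is.na(idx)], collapse = ", "), " (", source, ")")
  }
  labels_df$label[idx]
}

#' Read a cohort from disk
#'
#' Reads every `*.tsv` matrix file in `dir` (except `labels.tsv`) together
#' with a labels table. With `type = "timeseries"` files are T x N time
#' series; a file whose row count is smaller than its column count triggers
#' an orientation warning (never a silent transpose). With `type =
#' "networks"` files are N x N adjacency matrices, checked for symmetry
#' (tolerance 1e-8) and `[-1, 1]` bounds; a zero or absent diagonal is
#' accepted and converted to the NaN sentinel with a warning.
#'
#' @param dir directory of per-subject files.
#' @param labels_file labels table (default `dir/labels.tsv`).
#' @param type `"timeseries"` or `"networks"`.
#' @return An [roi_cohort()] or [fn_cohort()].
#' @export
read_cohort <- function(dir, labels_file = file.path(dir, "labels.tsv"),
                        type = c("timeseries", "networks")) {
  type <- match.arg(type)
  files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  files <- files[basename(files) != "labels.tsv"]
  if (!length(files)) stop("no subject .tsv files found in ", dir)
  ids <- sub("\\.tsv$", "", basename(files))
  labels <- match_labels(ids, read_labels(labels_file), labels_file)
  if (type == "timeseries") {
    series <- lapply(files, function(f) {
      m <- as.matrix(utils::read.delim(f, check.names = FALSE))
      if (nrow(m) < ncol(m)) {
        warning("file ", f, " has fewer rows (timepoints) than columns (ROIs); ",
                "check orientation — rows must be timepoints")
      }
      dimnames(m) <- NULL
      m
    })
    ns <- vapply(series, ncol, integer(1))
    if (length(unique(ns)) != 1L) {
      bad <- files[ns != stats::median(ns)]
      stop("dimension mismatch: file(s) ", paste(bad, collapse = ", "),
           " disagree on the number of ROI columns")
    }
    return(roi_cohort(series, ids, labels))
  }
  nets <- lapply(files, function(f) {
    m <- as.matrix(utils::read.delim(f, header = FALSE,
                                     na.strings = c("NA", "NaN", "nan")))
    dimnames(m) <- NULL
    if (nrow(m) != ncol(m)) {
      stop("dimension mismatch: adjacency file ", f, " is not square")
    }
    d <- diag(m)
    if (all(is.na(d))) {
      # NaN diagonal: the expected convention
    } else if (all(d == 0, na.rm = TRUE)) {
      warning("adjacency file ", f, " has a zero diagonal; converting to NaN")
    } else {
      warning("adjacency file ", f, " has a non-NaN, non-zero diagonal; ",
              "self-links are not interpretable and were discarded")
    }
    diag(m) <- NA_real_
    m
  })
  fn_cohort(nets, ids, labels)
}

#' Write a cohort's networks as delimited adjacency matrices
#'
#' One N x N tab-delimited file per subject with `NaN` on the diagonal,
#' plus `labels.tsv`.
#'
#' @param cohort an [fn_cohort()].
#' @param dir output directory.
#' @return Invisibly, the files written.
#' @export
write_networks <- function(cohort, dir) {
  stopifnot(inherits(cohort, "fn_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- vapply(seq_along(cohort$networks), function(s) {
    path <- file.path(dir, paste0(cohort$subject_id[s], ".tsv"))
    m <- cohort$networks[[s]]
    txt <- format(m, digits = 15, trim = TRUE)
    txt[is.na(m)] <- "NaN"
    utils::write.table(txt, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    path
  }, character(1))
  lab_path <- file.path(dir, "labels.tsv")
  utils::write.table(
    data.frame(subject_id = cohort$subject_id, label = cohort$label),
    lab_path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(c(files, lab_path))
}

#' Read an ROI metadata table
#'
#' @param path tab-delimited file with columns `index`, `name`, `x`, `y`,
#'   `z` (MNI mm) and `network` (intrinsic-connectivity-network membership).
#' @return Validated data.frame ordered by index.
#' @export
read_roi_metadata <- function(path) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("index", "name", "x", "y", "z", "network")
  if (!all(need %in% names(meta))) {
    stop("ROI metadata must have columns: ", paste(need, collapse = ", "))
  }
  meta <- meta[order(meta$index), ]
  if (!identical(as.integer(meta$index), seq_len(nrow(meta)))) {
    stop("ROI indices must be contiguous 1..N")
  }
  if (!all(is.finite(meta$x) & is.finite(meta$y) & is.finite(meta$z))) {
    stop("ROI coordinates must be finite")
  }
  meta
}

#' Write a dysconnected network as a sorted edge-list table
#'
#' Columns `roi_i`, `roi_j`, `t_value` with 1-based indices, sorted by
#' (i, j); identical networks produce byte-identical files.
#'
#' @param net a `dysconn`.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "dysconn"))
  df <- data.frame(
    roi_i = net$edges[, 1],
    roi_j = net$edges[, 2],
    t_value = sprintf("%.6g", net$t_values)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a JSON summary with deterministic layout
#'
#' Keys sorted, floats at 6 significant figures, scalars unboxed.
#'
#' @param x a named list.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_summary_json <- function(x, path) {
  sort_keys <- function(v) {
    if (is.list(v) && !is.null(names(v)) && length(v)) {
      v <- v[order(names(v))]
      lapply(v, sort_keys)
    } else {
      v
    }
  }
  jsonlite::write_json(sort_keys(x), path, auto_unbox = TRUE, digits = 6,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Export a dysconnected network for BrainNet Viewer
#'
#' Writes `<prefix>.edge` (N x N whitespace-delimited matrix holding the
#' selected edges' t-values, 0 elsewhere) and `<prefix>.node` (one row per
#' ROI: `x y z color size label`, color = network membership index, size =
#' node degree in the dysconnected network).
#'
#' @param net a `dysconn`.
#' @param roi_metadata data.frame from [read_roi_metadata()] covering all
#'   `net$n_rois` ROIs.
#' @param prefix output path prefix.
#' @return Invisibly, the two paths written.
#' @export
write_brainnet <- function(net, roi_metadata, prefix) {
  stopifnot(inherits(net, "dysconn"), nrow(roi_metadata) == net$n_rois)
  n <- net$n_rois
  em <- matrix(0, n, n)
  if (net$n_edges > 0) {
    em[net$edges] <- net$t_values
    em[net$edges[, c(2, 1), drop = FALSE]] <- net$t_values
  }
  edge_path <- paste0(prefix, ".edge")
  utils::write.table(format(em, digits = 6, trim = TRUE), edge_path,
                     sep = " ", quote = FALSE, row.names = FALSE, col.names = FALSE)
  deg <- network_degree_summary(net, n)$degrees
  color <- as.integer(factor(roi_metadata$network))
  node_path <- paste0(prefix, ".node")
  node <- data.frame(
    x = roi_metadata$x, y = roi_metadata$y, z = roi_metadata$z,
    color = color, size = deg,
    label = gsub("[[:space:]]+", "_", roi_metadata$name)
  )
  utils::write.table(node, node_path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(edge_path, node_path))
}
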