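# Internal helpers: seeded evaluation, edge indexing, union-find.

#' Evaluate an expression under a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

#' Derive a stream seed from a base seed and a small context index.
#'
#' XOR keeps derived seeds inside 32-bit integer range and makes streams
#' order-independent (subject 5's stream is the same whether classified
#' first or last).
#' @noRd
derive_seed <- function(base_seed, index) {
  bitwXor(as.integer(base_seed), as.integer(index))
}

#' Upper-triangle (i < j) index pairs of an N x N matrix, 1-based
#' @noRd
edge_pairs <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  colnames(idx) <- c("i", "j")
  idx
}

#' Stack a list of symmetric N x N matrices into a subjects x edges matrix
#' (upper triangle, row-major in (i, j)).
#' @noRd
edge_matrix <- function(mats) {
  n <- nrow(mats[[1]])
  pairs <- edge_pairs(n)
  lin <- (pairs[, "j"] - 1L) * n + pairs[, "i"]
  W <- t(vapply(mats, function(m) m[lin], numeric(nrow(pairs))))
  attr(W, "n_rois") <- n
  attr(W, "pairs") <- pairs
  W
}

#' Rebuild a symmetric matrix from an edge vector (upper-triangle order),
#' with `diag_value` on the diagonal.
#' @noRd
edges_to_matrix <- function(values, n, diag_value = NA_real_) {
  m <- matrix(0, n, n)
  pairs <- edge_pairs(n)
  m[cbind(pairs[, 1], pairs[, 2])] <- values
  m[cbind(pairs[, 2], pairs[, 1])] <- values
  diag(m) <- diag_value
  m
}

#' Maximum connected-component intensity of a weighted edge set.
#'
#' Union-find over the edge list; intensity of a component is the sum of its
#' edge weights. Returns 0 for an empty edge set. This is the permutation-null
#' hot path; the user-facing component extraction goes through igraph and the
#' two are cross-checked in the test suite.
#' @noRd
max_component_intensity <- function(ei, ej, w, n_nodes) {
  m <- length(ei)
  if (m == 0L) {
    return(0)
  }
  parent <- seq_len(n_nodes)
  find_root <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (k in seq_len(m)) {
    ri <- find_root(ei[k])
    rj <- find_root(ej[k])
    if (ri != rj) parent[ri] <- rj
  }
  roots <- vapply(ei, find_root, integer(1))
  max(rowsum(w, group = roots))
}
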