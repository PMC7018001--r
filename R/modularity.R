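#' Modularity matrix of a graph
#'
#' Computes Newman's modularity matrix \eqn{B = A - g g^T / 2m}, where `A` is
#' the (weighted) adjacency matrix, `g` the weighted degree vector and `2m` the
#' total edge weight. `B` is symmetric and its rows and columns sum to zero;
#' quadratic forms of community indicator vectors over `B` give `2m Q`.
#'
#' @param graph a [mod_graph()].
#' @return An object of class `modularity_matrix`: list with `B` (dense n x n),
#'   `m2` (the `2m` normalizer), `n`, `nodes`, and `threshold`/`retained_pairs`
#'   set when the matrix has been sparsified by [threshold_matrix()].
#' @examples
#' B <- modularity_matrix(mod_graph(c("a","b","c"), c("b","c","a")))
#' range(rowSums(B$B))  # zero row sums
#' @export
modularity_matrix <- function(graph) {
  stopifnot(inherits(graph, "mod_graph"))
  if (graph$m2 <= 0) {
    stop("graph has no edges (2m = 0); modularity matrix undefined",
         call. = FALSE)
  }
  g <- graph$degree
  structure(
    list(B = graph$A - outer(g, g) / graph$m2, m2 = graph$m2, n = graph$n,
         nodes = graph$nodes, threshold = 0, retained_pairs = NA_integer_),
    class = "modularity_matrix"
  )
}

#' @export
print.modularity_matrix <- function(x, ...) {
  cat(sprintf("Modularity matrix: %d x %d, 2m = %g", x$n, x$n, x$m2))
  if (!is.na(x$retained_pairs)) {
    cat(sprintf(", thresholded at %g (%d retained pairs)",
                x$threshold, x$retained_pairs))
  }
  cat("\n")
  invisible(x)
}

.check_labels <- function(labels, n) {
  labels <- as.integer(labels)
  if (length(labels) != n) {
    stop("partition has ", length(labels), " labels but the graph has ", n,
         " nodes", call. = FALSE)
  }
  if (anyNA(labels) || any(labels < 1L)) {
    stop("community labels must be positive integers", call. = FALSE)
  }
  labels
}

#' Modularity of a partition
#'
#' Evaluates \eqn{Q = (2m)^{-1} \sum_{ij} B_{ij}\, \delta(c_i, c_j)}, the
#' fraction of edge weight falling within communities minus its expectation
#' under the degree-preserving null model. The double sum includes the
#' diagonal, the standard Newman convention (excluding it only shifts Q by a
#' partition-independent constant).
#'
#' @param B a [modularity_matrix()]. Evaluation normally uses the original,
#'   unthresholded matrix even when optimization used a thresholded one.
#' @param labels integer community label per node (1-based). A one-hot matrix
#'   with one row per node is also accepted.
#' @return The modularity Q, a number in \[-1, 1\]; 0 for the one-community
#'   partition.
#' @export
modularity_score <- function(B, labels) {
  stopifnot(inherits(B, "modularity_matrix"))
  if (is.matrix(labels)) labels <- onehot_to_labels(labels)
  labels <- .check_labels(labels, B$n)
  q <- 0
  for (c in unique(labels)) {
    idx <- which(labels == c)
    q <- q + sum(B$B[idx, idx])
  }
  q / B$m2
}

#' Modularity of a two-community spin assignment
#'
#' For a spin vector \eqn{s \in \{-1,+1\}^n} encoding at most two communities,
#' \eqn{Q = (2m)^{-1} \sum_{ij} B_{ij} (s_i s_j + 1)/2}, which simplifies to
#' \eqn{(4m)^{-1} s^T B s} because the rows of B sum to zero.
#'
#' @param B a [modularity_matrix()].
#' @param s spin vector with entries in `{-1, +1}`.
#' @return Q of the induced two-part partition.
#' @export
modularity_spin <- function(B, s) {
  stopifnot(inherits(B, "modularity_matrix"))
  s <- .check_spins(B, s)
  drop(crossprod(s, B$B %*% s)) / (2 * B$m2)
}

.check_spins <- function(B, s) {
  s <- as.numeric(s)
  if (length(s) != B$n) {
    stop("spin vector length ", length(s), " != n = ", B$n, call. = FALSE)
  }
  if (!all(s %in% c(-1, 1))) {
    stop("spin entries must be -1 or +1", call. = FALSE)
  }
  s
}

#' Spin/binary quadratic-form identity
#'
#' Under the substitution \eqn{x = (s + 1)/2}, the zero row sums of B collapse
#' the cross terms so that \eqn{s^T B s = 4\, x^T B x}: the Ising (spin) and
#' QUBO (binary) formulations of two-community modularity maximization are the
#' same objective. Returns both sides for inspection or testing.
#'
#' @param B a [modularity_matrix()].
#' @param s spin vector with entries in `{-1, +1}`.
#' @return Named numeric vector `c(ising = s^T B s, qubo = 4 x^T B x)`.
#' @export
ising_qubo_identity <- function(B, s) {
  stopifnot(inherits(B, "modularity_matrix"))
  s <- .check_spins(B, s)
  x <- (s + 1) / 2
  c(ising = drop(crossprod(s, B$B %*% s)),
    qubo = 4 * drop(crossprod(x, B$B %*% x)))
}

#' Threshold a modularity matrix
#'
#' Zeroes every off-diagonal entry with \eqn{|B_{ij}| \le t} (strict `>` keeps
#' an entry), preserving the diagonal. Thresholding sparsifies the QUBO built
#' from B — fewer couplers, smaller embedded problems — while partition quality
#' is still evaluated against the original matrix, so moderate thresholds leave
#' the recovered community structure unchanged.
#'
#' @param B a [modularity_matrix()].
#' @param t nonnegative threshold.
#' @return A `modularity_matrix` whose `threshold` and `retained_pairs` fields
#'   record the provenance; `retained_pairs` counts upper-triangle pairs (i<j)
#'   with \eqn{|B_{ij}| > t}.
#' @examples
#' B <- modularity_matrix(load_benchmark("zachary"))
#' threshold_matrix(B, 0.06)$retained_pairs  # 334
#' @export
threshold_matrix <- function(B, t) {
  stopifnot(inherits(B, "modularity_matrix"))
  t <- as.numeric(t)[1L]
  if (is.na(t) || t < 0) stop("threshold must be >= 0", call. = FALSE)
  Bt <- B$B
  keep <- abs(Bt) > t
  diag(keep) <- TRUE
  Bt[!keep] <- 0
  out <- B
  out$B <- Bt
  out$threshold <- t
  out$retained_pairs <- sum(keep[upper.tri(keep)])
  out
}

#' Convert a one-hot matrix to community labels
#'
#' @param X binary n x k matrix with exactly one 1 per row.
#' @return Integer label vector (1-based column index of the set bit).
#' @export
onehot_to_labels <- function(X) {
  X <- as.matrix(X)
  if (!all(X %in% c(0, 1)) || !all(rowSums(X) == 1)) {
    stop("not a one-hot matrix: every row must have exactly one 1",
         call. = FALSE)
  }
  max.col(X, ties.method = "first")
}

#' Convert community labels to a one-hot matrix
#'
#' @param labels integer labels, 1-based.
#' @param k number of columns (communities); defaults to `max(labels)`.
#' @return Binary n x k matrix X with `X[i, labels[i]] = 1`.
#' @export
labels_to_onehot <- function(labels, k = max(labels)) {
  labels <- as.integer(labels)
  if (any(labels < 1L) || any(labels > k)) {
    stop("labels must lie in 1..k", call. = FALSE)
  }
  X <- matrix(0L, length(labels), k)
  X[cbind(seq_along(labels), labels)] <- 1L
  X
}
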