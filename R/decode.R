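#' Decode a QUBO bitstring into a partition
#'
#' Interprets a length `n * k` assignment as the column-stacked one-hot matrix
#' X (variable `(i, j)` at index `i + (j - 1) * n`). A super-node with exactly
#' one set bit selects that node's community; otherwise the assignment is
#' infeasible and the violating super-nodes are reported.
#'
#' @param bits 0/1 vector of length `n * k`.
#' @param n number of nodes.
#' @param k number of community slots.
#' @return A list: `feasible` (logical); if feasible, `labels` (1-based
#'   community per node); if not, `violations`, a data frame of offending
#'   super-nodes with their set-bit counts.
#' @examples
#' decode_assignment(c(1, 0, 0, 1), n = 2, k = 2)$labels  # 1 2
#' @export
decode_assignment <- function(bits, n, k) {
  n <- as.integer(n); k <- as.integer(k)
  bits <- as.integer(bits)
  if (length(bits) != n * k) {
    stop("assignment length ", length(bits), " != n * k = ", n * k,
         call. = FALSE)
  }
  if (!all(bits %in% c(0L, 1L))) stop("assignment must be 0/1", call. = FALSE)
  X <- matrix(bits, nrow = n, ncol = k)
  nset <- rowSums(X)
  if (all(nset == 1L)) {
    list(feasible = TRUE,
         labels = max.col(X, ties.method = "first"),
         violations = NULL)
  } else {
    bad <- which(nset != 1L)
    list(feasible = FALSE, labels = NULL,
         violations = data.frame(node = bad, bits_set = nset[bad]))
  }
}

#' Canonicalize community labels
#'
#' Relabels communities 1, 2, ... in order of first appearance by node index
#' and drops empty labels. Idempotent; any two label-permuted encodings of the
#' same partition map to the identical canonical form.
#'
#' @param labels integer community labels.
#' @return Canonical integer labels.
#' @examples
#' canonicalize_partition(c(3, 3, 1, 2))  # 1 1 2 3
#' @export
canonicalize_partition <- function(labels) {
  labels <- as.integer(labels)
  match(labels, unique(labels))
}

# Greedy one-hot repair: each violating super-node is assigned, in node order,
# to the community maximizing the modularity gain given all other current
# assignments (multi-set nodes choose among their set bits).
.repair_assignment <- function(X, B) {
  n <- nrow(X); k <- ncol(X)
  nset <- rowSums(X)
  labels <- integer(n)
  ok <- nset == 1L
  labels[ok] <- max.col(X[, , drop = FALSE], ties.method = "first")[ok]
  for (i in which(!ok)) {
    cand <- if (nset[i] >= 2L) which(X[i, ] == 1L) else seq_len(k)
    gain <- vapply(cand, function(j) {
      members <- which(labels == j)
      2 * sum(B$B[i, members]) + B$B[i, i]
    }, 0)
    labels[i] <- cand[which.max(gain)]
  }
  labels
}

#' Select the best partition from a sample set
#'
#' Discards infeasible samples (unless `repair_infeasible`), decodes the rest,
#' and returns the partition maximizing modularity evaluated on `B_original` —
#' the unthresholded matrix, even when the annealed QUBO was built from a
#' thresholded one. Ties in Q break toward fewer non-empty communities, then
#' the lexicographically smallest canonical labeling.
#'
#' @param samples a `qubo_samples` object.
#' @param B_original the original (unthresholded) [modularity_matrix()].
#' @param n,k dimensions of the encoding.
#' @param repair_infeasible if `TRUE`, infeasible samples are repaired by a
#'   greedy per-super-node assignment instead of discarded. Off by default:
#'   silent repair masks an underpowered penalty.
#' @param select `"modularity"` (default) picks the sample maximizing Q on
#'   `B_original`; `"energy"` picks the minimum-energy sample — the annealed
#'   problem's own answer, which matters when that problem was built from a
#'   thresholded matrix and its optimum differs from the unthresholded one.
#' @return A list: `labels` (canonical), `modularity`, `n_communities`,
#'   `feasible_fraction` (occurrence-weighted), `energy` (of the selected
#'   sample), `n_feasible`.
#' @export
best_partition <- function(samples, B_original, n, k,
                           repair_infeasible = FALSE,
                           select = c("modularity", "energy")) {
  select <- match.arg(select)
  stopifnot(inherits(samples, "qubo_samples"),
            inherits(B_original, "modularity_matrix"))
  n <- as.integer(n); k <- as.integer(k)
  ns <- nrow(samples$bits)
  if (ns < 1L) stop("empty sample set", call. = FALSE)
  labs <- vector("list", ns)
  feas <- logical(ns)
  for (r in seq_len(ns)) {
    d <- decode_assignment(samples$bits[r, ], n, k)
    feas[r] <- d$feasible
    if (d$feasible) {
      labs[[r]] <- d$labels
    } else if (repair_infeasible) {
      labs[[r]] <- .repair_assignment(matrix(samples$bits[r, ], n, k),
                                      B_original)
    }
  }
  feasible_fraction <- sum(samples$n_occ[feas]) / sum(samples$n_occ)
  use <- if (repair_infeasible) seq_len(ns) else which(feas)
  if (!length(use)) {
    stop("all ", ns, " sampled states violate the one-hot constraint; ",
         "increase the penalty magnitude", call. = FALSE)
  }
  q <- vapply(use, function(r) modularity_score(B_original, labs[[r]]), 0)
  ncom <- vapply(use, function(r) length(unique(labs[[r]])), 0L)
  key <- vapply(use, function(r)
    paste0(canonicalize_partition(labs[[r]]), collapse = ","), "")
  best <- if (select == "modularity") {
    use[order(-q, ncom, key)][1L]       # samples are already energy-sorted,
  } else {                              # so use[1] is the min-energy sample;
    use[order(samples$energy[use], ncom, key)][1L]  # ties break identically
  }
  bi <- match(best, use)
  list(labels = canonicalize_partition(labs[[best]]),
       modularity = q[bi],
       n_communities = ncom[bi],
       feasible_fraction = feasible_fraction,
       energy = samples$energy[best],
       n_feasible = sum(feas))
}
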