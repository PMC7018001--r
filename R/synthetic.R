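#' Planted-partition random graph
#'
#' Generates an undirected simple graph with known block structure: each
#' within-block node pair is an edge with probability `p_in`, each cross-block
#' pair with probability `p_out < p_in`. Used to validate that the pipeline
#' recovers ground-truth communities.
#'
#' @param block_sizes integer vector of block sizes.
#' @param p_in within-block edge probability.
#' @param p_out cross-block edge probability; must be `< p_in`.
#' @param seed optional integer; when given, `set.seed(seed)` is called so the
#'   draw is reproducible.
#' @return A list: `graph` (a [mod_graph()] whose node set includes isolated
#'   nodes, in block order) and `labels` (ground-truth block per node).
#' @examples
#' pp <- planted_partition(c(3, 3), p_in = 1, p_out = 0)  # two triangles
#' pp$graph$n
#' @export
planted_partition <- function(block_sizes, p_in, p_out, seed = NULL) {
  block_sizes <- as.integer(block_sizes)
  if (any(block_sizes < 1L) || length(block_sizes) < 1L) {
    stop("block sizes must be positive", call. = FALSE)
  }
  if (!(p_out >= 0 && p_in <= 1 && p_out < p_in)) {
    stop("need 0 <= p_out < p_in <= 1 (p_out >= p_in leaves no community ",
         "structure)", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- sum(block_sizes)
  labels <- rep(seq_along(block_sizes), block_sizes)
  nodes <- sprintf("v%03d", seq_len(n))
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  p <- ifelse(labels[ut[, 1L]] == labels[ut[, 2L]], p_in, p_out)
  keep <- stats::runif(nrow(ut)) < p
  if (!any(keep)) stop("drawn graph has no edges; raise p_in", call. = FALSE)
  g <- mod_graph(nodes[ut[keep, 1L]], nodes[ut[keep, 2L]], nodes = nodes)
  list(graph = g, labels = labels)
}

#' Registry of small worked-example graphs
#'
#' Returns named toy graphs, each with its exact maximum-modularity partition
#' (computed by [brute_force_best_partition()]) attached as the oracle answer.
#'
#' @return Named list; each element has `graph`, `oracle_labels`, `oracle_q`.
#' @export
toy_graphs <- function() {
  gs <- list(
    triangle = mod_graph(c("a", "b", "c"), c("b", "c", "a")),
    path_4 = mod_graph(c("a", "b", "c"), c("b", "c", "d")),
    barbell = mod_graph(c("a", "b", "c", "d", "e", "f", "c"),
                        c("b", "c", "a", "e", "f", "d", "d")),
    two_triangles = mod_graph(c("a", "b", "c", "d", "e", "f"),
                              c("b", "c", "a", "e", "f", "d"))
  )
  lapply(gs, function(g) {
    o <- brute_force_best_partition(g)
    list(graph = g, oracle_labels = o$labels, oracle_q = o$modularity)
  })
}

# next restricted-growth string after `a` (or NULL when exhausted)
.next_rgs <- function(a) {
  n <- length(a)
  b <- c(0L, cummax(a))[seq_len(n)]   # b[i] = max(a[1..i-1]), with a[1] = 1
  for (i in rev(seq_len(n))) {
    if (i > 1L && a[i] <= b[i]) {
      a[i] <- a[i] + 1L
      if (i < n) a[(i + 1L):n] <- 1L
      return(a)
    }
  }
  NULL
}

#' Exact maximum-modularity partition by exhaustive search
#'
#' Enumerates every set partition of the nodes (as restricted-growth strings,
#' so each partition is visited exactly once) and returns the exact modularity
#' maximizer. The number of set partitions is the Bell number, so the search
#' is capped at `max_n` nodes (B_10 = 115975).
#'
#' @param graph a [mod_graph()].
#' @param max_n refusal cap on the node count (default 10).
#' @return A list: `labels` (canonical optimal partition), `modularity`
#'   (its Q), `n_partitions` (number of set partitions scored).
#' @export
brute_force_best_partition <- function(graph, max_n = 10) {
  stopifnot(inherits(graph, "mod_graph"))
  if (graph$n > max_n) {
    stop("brute-force search refuses n > ", max_n, " (got ", graph$n,
         "); the set-partition count grows as the Bell number", call. = FALSE)
  }
  B <- modularity_matrix(graph)
  n <- graph$n
  a <- rep(1L, n)
  best_q <- -Inf
  best <- a
  count <- 0L
  repeat {
    count <- count + 1L
    S <- rowsum(B$B, a)
    q <- sum(S[cbind(a, seq_len(n))]) / B$m2
    if (q > best_q + 1e-12) {
      best_q <- q
      best <- a
    }
    a <- .next_rgs(a)
    if (is.null(a)) break
  }
  list(labels = canonicalize_partition(best), modularity = best_q,
       n_partitions = count)
}
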