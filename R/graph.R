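#' Construct an undirected weighted graph
#'
#' Builds the package's graph container from parallel edge vectors. Node
#' identifiers are arbitrary strings mapped to dense indices in order of first
#' appearance; that order is fixed at construction and preserved through all
#' downstream matrices. Duplicate edges collapse by summing their weights
#' (coappearance-count semantics) and self-loops are dropped with a warning,
#' since the adjacency matrix is defined with a zero diagonal.
#'
#' @param from,to character (or coercible) vectors of endpoint identifiers.
#' @param weight numeric vector of positive edge weights, recycled; default 1.
#' @param nodes optional character vector fixing the node set and order;
#'   must contain every endpoint. Defaults to first-appearance order.
#' @return An object of class `mod_graph`: a list with elements `nodes`
#'   (character), `n`, `A` (dense symmetric adjacency with zero diagonal),
#'   `degree` (weighted degrees \eqn{g_i = \sum_j A_{ij}}) and `m2`
#'   (total weight \eqn{2m = \sum_i g_i}).
#' @examples
#' g <- mod_graph(c("a", "b", "c"), c("b", "c", "a"))
#' g$m2  # 6 for an unweighted triangle
#' @export
mod_graph <- function(from, to, weight = 1, nodes = NULL) {
  from <- as.character(from)
  to <- as.character(to)
  if (length(from) != length(to)) {
    stop("'from' and 'to' must have equal length", call. = FALSE)
  }
  weight <- rep_len(as.numeric(weight), length(from))
  if (any(!is.finite(weight)) || any(weight <= 0)) {
    stop("edge weights must be finite and positive", call. = FALSE)
  }
  loops <- from == to
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped (adjacency diagonal is zero)",
            call. = FALSE)
    from <- from[!loops]; to <- to[!loops]; weight <- weight[!loops]
  }
  if (is.null(nodes)) {
    # first-appearance order over the interleaved endpoint stream
    ends <- character(2L * length(from))
    ends[c(TRUE, FALSE)] <- from
    ends[c(FALSE, TRUE)] <- to
    nodes <- unique(ends)
  } else {
    nodes <- as.character(nodes)
    if (anyDuplicated(nodes)) stop("'nodes' contains duplicates", call. = FALSE)
    if (!all(c(from, to) %in% nodes)) {
      stop("'nodes' must contain every edge endpoint", call. = FALSE)
    }
  }
  n <- length(nodes)
  i <- match(from, nodes)
  j <- match(to, nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (e in seq_along(i)) {     # sums duplicates by construction
    A[i[e], j[e]] <- A[i[e], j[e]] + weight[e]
    A[j[e], i[e]] <- A[j[e], i[e]] + weight[e]
  }
  structure(
    list(nodes = nodes, n = n, A = A, degree = rowSums(A), m2 = sum(A)),
    class = "mod_graph"
  )
}

#' @export
print.mod_graph <- function(x, ...) {
  cat(sprintf("Undirected graph: %d nodes, %d edges, total weight 2m = %g\n",
              x$n, sum(x$A[upper.tri(x$A)] > 0), x$m2))
  invisible(x)
}

#' Number of distinct edges in a graph
#'
#' @param graph a [mod_graph()].
#' @return Count of unordered node pairs with nonzero adjacency.
#' @export
n_edges <- function(graph) {
  stopifnot(inherits(graph, "mod_graph"))
  sum(graph$A[upper.tri(graph$A)] != 0)
}

#' Read a graph from a whitespace-separated edge list
#'
#' Each non-comment line holds `node_u node_v [weight]`. Lines starting with
#' `#` (and blank lines) are ignored. Nodes are ordered by first appearance;
#' duplicate edges sum their weights; self-loops are dropped with a warning.
#'
#' @param path path to the edge-list file.
#' @param weighted if `TRUE` (default) a third column, when present, is read
#'   as the edge weight; if `FALSE` any weight column is ignored and all
#'   weights are set to 1 (binarized).
#' @return A [mod_graph()].
#' @export
read_edge_list <- function(path, weighted = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  toks <- strsplit(trimws(lines[keep]), "\\s+")
  nf <- lengths(toks)
  bad <- which(nf < 2L | nf > 3L)
  if (length(bad)) {
    stop(sprintf("malformed edge list line %d: '%s' (need 2 or 3 fields)",
                 idx[bad[1L]], lines[idx[bad[1L]]]), call. = FALSE)
  }
  from <- vapply(toks, `[`, "", 1L)
  to <- vapply(toks, `[`, "", 2L)
  w <- rep(1, length(toks))
  if (weighted && any(nf == 3L)) {
    wraw <- vapply(toks, function(t) if (length(t) == 3L) t[3L] else "1", "")
    w <- suppressWarnings(as.numeric(wraw))
    if (anyNA(w)) {
      b <- which(is.na(w))[1L]
      stop(sprintf("malformed weight on line %d: '%s'", idx[b], lines[idx[b]]),
           call. = FALSE)
    }
    if (any(w <= 0)) {
      b <- which(w <= 0)[1L]
      stop(sprintf("non-positive weight on line %d: '%s'", idx[b], lines[idx[b]]),
           call. = FALSE)
    }
  }
  if (!length(from)) stop("edge list is empty: ", path, call. = FALSE)
  mod_graph(from, to, w)
}

#' Write a graph as a whitespace-separated edge list
#'
#' Edges are written sorted by node index so that re-reading reproduces a graph
#' whose name-aligned adjacency matrix is identical. Weights are written only
#' when some edge weight differs from 1.
#'
#' @param graph a [mod_graph()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  stopifnot(inherits(graph, "mod_graph"))
  ut <- which(upper.tri(graph$A) & graph$A != 0, arr.ind = TRUE)
  ut <- ut[order(ut[, 1L], ut[, 2L]), , drop = FALSE]
  u <- graph$nodes[ut[, 1L]]
  v <- graph$nodes[ut[, 2L]]
  w <- graph$A[ut]
  lines <- if (all(w == 1)) paste(u, v) else paste(u, v, format(w, digits = 15))
  writeLines(lines, path)
  invisible(path)
}

#' Read a graph from a GML file
#'
#' Parses the standard GML dialect (as produced by common graph libraries) via
#' \pkg{igraph} and converts to the package's graph container, honoring an edge
#' `weight` attribute when present. Node labels are used as identifiers when
#' available, otherwise GML ids.
#'
#' @param path path to the GML file.
#' @param weighted if `FALSE`, edge weights are ignored (all set to 1).
#' @return A [mod_graph()].
#' @export
read_gml <- function(path, weighted = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ig <- tryCatch(
    igraph::read_graph(path, format = "gml"),
    error = function(e) stop("cannot parse GML file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  el <- igraph::as_edgelist(ig, names = TRUE)
  if (!nrow(el)) stop("GML graph has no edges: ", path, call. = FALSE)
  w <- if (weighted && "weight" %in% igraph::edge_attr_names(ig)) {
    igraph::E(ig)$weight
  } else 1
  nodes <- igraph::vertex_attr(ig, "name")
  if (is.null(nodes)) nodes <- as.character(seq_len(igraph::vcount(ig)))
  mod_graph(as.character(el[, 1L]), as.character(el[, 2L]), w,
            nodes = as.character(nodes))
}

#' Convert to an igraph object
#'
#' @param graph a [mod_graph()].
#' @return An [igraph::graph_from_adjacency_matrix()] undirected weighted graph
#'   with the same node order.
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "mod_graph"))
  igraph::graph_from_adjacency_matrix(graph$A, mode = "undirected",
                                      weighted = TRUE)
}
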