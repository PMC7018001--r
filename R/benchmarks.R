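# Registry of the classic community-detection benchmark graphs. Zachary and
# LesMiserables ship with the package; the others are looked up in extdata so
# users can drop in the standard public edge lists under the same names.
# `penalty` is the hand-tuned one-hot penalty magnitude reported for the
# classical-annealer runs on each graph; `n`/`edges` are the published sizes.
.benchmark_registry <- list(
  zachary        = list(file = "zachary.edgelist",        weighted = FALSE,
                        penalty = 5,  n = 34,  edges = 78),
  dolphins       = list(file = "dolphins.edgelist",       weighted = FALSE,
                        penalty = 5,  n = 62,  edges = 159),
  lesmiserables  = list(file = "lesmiserables.edgelist",  weighted = FALSE,
                        penalty = 7,  n = 77,  edges = 254),
  politicalbooks = list(file = "politicalbooks.edgelist", weighted = FALSE,
                        penalty = 10, n = 105, edges = 441),
  jazz           = list(file = "jazz.edgelist",           weighted = FALSE,
                        penalty = 20, n = 198, edges = 2742),
  elegans        = list(file = "elegans.edgelist",        weighted = FALSE,
                        penalty = 20, n = 453, edges = 2040)
)

#' List available benchmark graphs
#'
#' @return Data frame with one row per registered benchmark: its name,
#'   published node and edge counts, whether it is weighted, the recommended
#'   one-hot penalty magnitude, and whether its fixture file is present in
#'   this installation.
#' @export
list_benchmarks <- function() {
  reg <- .benchmark_registry
  data.frame(
    name = names(reg),
    n = vapply(reg, `[[`, 0, "n"),
    edges = vapply(reg, `[[`, 0, "edges"),
    weighted = vapply(reg, `[[`, TRUE, "weighted"),
    penalty = vapply(reg, `[[`, 0, "penalty"),
    available = vapply(reg, function(b)
      nzchar(system.file("extdata", b$file, package = "modcom")), TRUE),
    row.names = NULL
  )
}

#' Load a bundled benchmark graph
#'
#' Loads one of the classic community-detection benchmarks by name. The Zachary
#' karate club (34 nodes, 78 edges, unweighted) and the Les Miserables
#' character coappearance network (77 nodes, 254 edges, weighted) are bundled;
#' the remaining registered names resolve only if the corresponding standard
#' public edge list has been placed in the package's `extdata` directory.
#'
#' @param name benchmark identifier; see [list_benchmarks()].
#' @param weighted load published edge weights where the benchmark has them
#'   (Les Miserables coappearance counts)? Default taken from the registry;
#'   pass `FALSE` to binarize.
#' @return A [mod_graph()] with attribute `"penalty"` giving the recommended
#'   one-hot penalty magnitude for this graph.
#' @examples
#' g <- load_benchmark("zachary")
#' c(g$n, n_edges(g))  # 34, 78
#' @export
load_benchmark <- function(name, weighted = NULL) {
  name <- tolower(as.character(name)[1L])
  if (!name %in% names(.benchmark_registry)) {
    stop("unknown benchmark '", name, "'; available: ",
         paste(names(.benchmark_registry), collapse = ", "), call. = FALSE)
  }
  b <- .benchmark_registry[[name]]
  path <- system.file("extdata", b$file, package = "modcom")
  if (!nzchar(path)) {
    have <- list_benchmarks()
    stop("no fixture file for benchmark '", name, "'; bundled benchmarks: ",
         paste(have$name[have$available], collapse = ", "),
         " (drop '", b$file, "' into the package extdata directory to enable it)",
         call. = FALSE)
  }
  if (is.null(weighted)) weighted <- b$weighted
  g <- read_edge_list(path, weighted = weighted)
  # the published hand-tuned magnitudes are on the unweighted (binary) scale;
  # a weighted load gets the coefficient-based default instead
  if (!weighted) attr(g, "penalty") <- b$penalty
  g
}
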