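# shared fixtures built in code

triangle_graph <- function() mod_graph(c("a", "b", "c"), c("b", "c", "a"))

# path a - b - c - d
path4_graph <- function() mod_graph(c("a", "b", "c"), c("b", "c", "d"))

# two triangles joined by one bridge edge
barbell_graph <- function() {
  mod_graph(c("a", "b", "c", "d", "e", "f", "c"),
            c("b", "c", "a", "e", "f", "d", "d"))
}

two_triangles_graph <- function() {
  mod_graph(c("a", "b", "c", "d", "e", "f"),
            c("b", "c", "a", "e", "f", "d"))
}

zachary <- function() load_benchmark("zachary")

# a minimal hand-built QUBO problem (bypasses build_qubo) for sampler tests
tiny_qubo <- function(linear, qi = integer(), qj = integer(), qv = numeric()) {
  structure(
    list(n_vars = length(linear), linear = as.numeric(linear),
         quad = list(i = as.integer(qi), j = as.integer(qj),
                     value = as.numeric(qv)),
         offset = 0, n = length(linear), k = 1L, beta = 1,
         penalty = rep(1, length(linear)),
         B = NULL),
    class = "qubo_problem"
  )
}

random_onehot <- function(n, k) {
  labels <- sample.int(k, n, replace = TRUE)
  as.integer(labels_to_onehot(labels, k))  # column-stacked bits
}

expect_same_partition <- function(a, b) {
  expect_identical(canonicalize_partition(a), canonicalize_partition(b))
}
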