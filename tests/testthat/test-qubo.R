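test_that("QUBO dimensions, validation and degenerate cases", {
  B <- modularity_matrix(triangle_graph())
  q <- build_qubo(B, k = 2)
  expect_equal(q$n_vars, 6)
  expect_error(build_qubo(B, k = 0), "positive")
  expect_error(build_qubo(B, k = 2, penalty = 0), "penalty")
  expect_error(build_qubo(B, k = 2, penalty = -1), "penalty")
  expect_error(build_qubo(B, k = 2, beta = -1), "beta")

  # single node, k = 2: both one-hot states degenerate by symmetry
  g1 <- mod_graph("a", "b")   # 2 nodes so B exists; isolate the symmetry on k
  B1 <- modularity_matrix(g1)
  q1 <- build_qubo(B1, k = 2, penalty = 3)
  e10 <- qubo_energy(q1, c(1, 1, 0, 0))  # both nodes in community 1
  e01 <- qubo_energy(q1, c(0, 0, 1, 1))  # both nodes in community 2
  expect_equal(e10, e01, tolerance = 1e-12)

  # k = 1: the penalty forces the all-ones assignment, decoded Q = 0
  qk1 <- build_qubo(B, k = 1, penalty = 3)
  gs <- exhaustive_solve(qk1)
  expect_equal(as.integer(gs$bits[1, ]), rep(1L, 3))
  expect_equal(modularity_score(B, decode_assignment(gs$bits[1, ], 3, 1)$labels),
               0)
})

test_that("energy of an assignment follows the coefficient sum convention", {
  B <- modularity_matrix(triangle_graph())
  q <- build_qubo(B, k = 2, penalty = 4)
  expect_equal(qubo_energy(q, rep(0, 6)), q$offset)
  expect_error(qubo_energy(q, rep(0, 5)), "length")
  expect_error(qubo_energy(q, c(2, rep(0, 5))), "0/1")
})

test_that("feasible one-hot energies equal -beta*2m*Q - sum(penalty)", {
  set.seed(11)
  for (rep in 1:5) {
    g <- planted_partition(c(4, 4), 0.9, 0.3, seed = rep)$graph
    B <- modularity_matrix(g)
    for (cfg in list(list(k = 3, beta = 1, t = 0),
                     list(k = 4, beta = 2.5, t = 0),
                     list(k = 3, beta = 1, t = 0.05))) {
      Bt <- threshold_matrix(B, cfg$t)
      q <- build_qubo(Bt, k = cfg$k, penalty = 2.2, beta = cfg$beta)
      for (draw in 1:10) {
        bits <- random_onehot(g$n, cfg$k)
        labels <- onehot_to_labels(matrix(bits, g$n, cfg$k))
        # Q on the matrix the problem was built from (the thresholded one)
        expected <- -cfg$beta * B$m2 * modularity_score(Bt, labels) -
          sum(q$penalty)
        expect_equal(qubo_energy(q, bits), expected, tolerance = 1e-9)
      }
    }
  }
})

test_that("energy is invariant under community-block relabeling", {
  g <- barbell_graph()
  B <- modularity_matrix(g)
  k <- 3
  q <- build_qubo(B, k = k, penalty = 3)
  set.seed(2)
  for (rep in 1:10) {
    bits <- matrix(random_onehot(g$n, k), g$n, k)
    perm <- sample.int(k)
    expect_equal(qubo_energy(q, as.integer(bits)),
                 qubo_energy(q, as.integer(bits[, perm])),
                 tolerance = 1e-12)
  }
})

test_that("minimum-energy feasible states are the brute-force maximizers", {
  g <- triangle_graph()
  B <- modularity_matrix(g)
  q <- build_qubo(B, k = 2, penalty = default_penalty(B))
  # full enumeration of all 2^6 assignments through the public energy op
  states <- as.matrix(expand.grid(rep(list(0:1), 6)))
  energies <- apply(states, 1, function(b) qubo_energy(q, b))
  feas <- apply(states, 1, function(b) decode_assignment(b, 3, 2)$feasible)
  best_e <- min(energies[feas])
  best_states <- states[feas & abs(energies - best_e) < 1e-9, , drop = FALSE]
  oracle <- brute_force_best_partition(g)
  for (r in seq_len(nrow(best_states))) {
    labels <- decode_assignment(best_states[r, ], 3, 2)$labels
    expect_equal(modularity_score(B, labels), oracle$modularity,
                 tolerance = 1e-9)
  }
})

test_that("with the default penalty the global minimizer is one-hot feasible", {
  for (g in list(triangle_graph(), path4_graph())) {
    B <- modularity_matrix(g)
    for (k in 2:3) {
      q <- build_qubo(B, k = k)  # default penalty bound
      if (q$n_vars > 16) next
      gs <- exhaustive_solve(q)
      for (r in seq_len(nrow(gs$bits))) {
        expect_true(decode_assignment(gs$bits[r, ], g$n, k)$feasible)
      }
    }
  }
})

test_that("infeasible assignments cost more than their repaired versions", {
  g <- path4_graph()
  B <- modularity_matrix(g)
  q <- build_qubo(B, k = 2, penalty = default_penalty(B))
  set.seed(3)
  for (rep in 1:20) {
    bits <- matrix(random_onehot(4, 2), 4, 2)
    node <- sample.int(4, 1)
    broken <- bits
    broken[node, ] <- 1L       # double assignment violates one-hot
    expect_gt(qubo_energy(q, as.integer(broken)),
              qubo_energy(q, as.integer(bits)))
    broken[node, ] <- 0L       # unassigned node also violates
    expect_gt(qubo_energy(q, as.integer(broken)),
              min(qubo_energy(q, as.integer(bits))))
  }
})

test_that("thresholded matrices shrink the coupling count", {
  B <- modularity_matrix(zachary())
  q_full <- build_qubo(B, k = 4, penalty = 5)
  q_thr <- build_qubo(threshold_matrix(B, 0.06), k = 4, penalty = 5)
  n_pen <- 34 * choose(4, 2)
  expect_equal(length(q_full$quad$value) - n_pen, 561 * 4)
  expect_equal(length(q_thr$quad$value) - n_pen, 334 * 4)
})
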