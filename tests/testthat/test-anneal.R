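test_that("single-variable problems anneal to the obvious optimum", {
  up <- tiny_qubo(5)    # positive linear term: bit stays off
  s <- simulated_anneal(up, num_reads = 20, anneal_schedule(50), seed = 1)
  expect_equal(as.integer(s$bits[1, ]), 0L)
  expect_equal(s$energy[1], 0)

  down <- tiny_qubo(-5) # negative linear term: bit turns on
  s <- simulated_anneal(down, num_reads = 20, anneal_schedule(50), seed = 1)
  expect_equal(as.integer(s$bits[1, ]), 1L)
  expect_equal(s$energy[1], -5)
})

test_that("hand-enumerable two-variable problem solves exactly", {
  # q11 = q22 = -1, q12 = +3: optimum is exactly one bit set (energy -1)
  p <- tiny_qubo(c(-1, -1), qi = 1, qj = 2, qv = 3)
  gs <- exhaustive_solve(p)
  expect_equal(gs$energy[1], -1)
  expect_equal(sort(rowSums(gs$bits)), c(1, 1))  # both single-bit states tie
  s <- simulated_anneal(p, num_reads = 10, anneal_schedule(100), seed = 2)
  expect_equal(s$energy[1], -1)
})

test_that("sampling is deterministic under a fixed seed", {
  B <- modularity_matrix(barbell_graph())
  p <- build_qubo(B, k = 2, penalty = 3)
  s1 <- simulated_anneal(p, num_reads = 50, anneal_schedule(200), seed = 9)
  s2 <- simulated_anneal(p, num_reads = 50, anneal_schedule(200), seed = 9)
  expect_identical(s1$bits, s2$bits)
  expect_identical(s1$energy, s2$energy)
  s3 <- simulated_anneal(p, num_reads = 50, anneal_schedule(200), seed = 10)
  expect_false(identical(s1$energy, s3$energy) && identical(s1$bits, s3$bits))
})

test_that("sample sets are energy-sorted, occurrence-counted and consistent", {
  B <- modularity_matrix(triangle_graph())
  p <- build_qubo(B, k = 2, penalty = 3)
  s <- simulated_anneal(p, num_reads = 100, anneal_schedule(200), seed = 4)
  expect_true(all(diff(s$energy) >= 0))
  expect_equal(sum(s$n_occ), 100)
  for (r in seq_len(nrow(s$bits))) {
    expect_equal(qubo_energy(p, s$bits[r, ]), s$energy[r], tolerance = 1e-9)
  }
})

test_that("exhaustive enumeration returns the full ground-state set", {
  flat <- tiny_qubo(rep(0, 3))   # every assignment ties at zero
  gs <- exhaustive_solve(flat)
  expect_equal(nrow(gs$bits), 8)
  expect_true(all(gs$energy == 0))
  big <- tiny_qubo(rep(-1, 23))
  expect_error(exhaustive_solve(big), "22")
})

test_that("annealed best energy matches the exhaustive minimum on small QUBOs", {
  cases <- list(list(g = triangle_graph(), k = 2),      # N = 6
                list(g = path4_graph(), k = 2),         # N = 8
                list(g = path4_graph(), k = 3),         # N = 12
                list(g = barbell_graph(), k = 2),       # N = 12
                list(g = two_triangles_graph(), k = 2)) # N = 12
  for (case in cases) {
    B <- modularity_matrix(case$g)
    p <- build_qubo(B, k = case$k)
    exact <- exhaustive_solve(p)$energy[1]
    for (seed in 1:3) {
      s <- simulated_anneal(p, num_reads = 100, anneal_schedule(2000),
                            seed = seed)
      expect_gte(s$energy[1], exact - 1e-9)
      expect_equal(s$energy[1], exact, tolerance = 1e-9)
    }
  }
})

test_that("more reads do not hurt the best energy found", {
  B <- modularity_matrix(barbell_graph())
  p <- build_qubo(B, k = 3, penalty = 2)
  mean_best <- function(nr) {
    mean(vapply(1:8, function(seed)
      simulated_anneal(p, nr, anneal_schedule(100), seed = seed)$energy[1], 0))
  }
  expect_lte(mean_best(30), mean_best(3) + 1e-12)
})

test_that("schedules validate and auto-scale to the coefficients", {
  expect_error(anneal_schedule(0), "sweeps")
  expect_error(anneal_schedule(10, c(2, 1)), "beta_start")
  expect_error(anneal_schedule(10, c(-1, 1)), "beta_start")
  B <- modularity_matrix(zachary())
  p <- build_qubo(B, k = 4, penalty = 5)
  br <- default_beta_range(p)
  expect_lt(br[1], br[2])
  expect_gt(br[1], 0)
  # hot end: worst single flip accepted with probability ~ 1/2
  worst <- max(abs(p$linear) +
                 vapply(seq_len(p$n_vars), function(v)
                   sum(abs(p$quad$value[p$quad$i == v | p$quad$j == v])), 0))
  expect_equal(br[1], log(2) / worst, tolerance = 1e-9)
})

test_that("the sampler contract validates plugin backends", {
  B <- modularity_matrix(triangle_graph())
  p <- build_qubo(B, k = 2, penalty = 3)

  good <- function(problem, ...) exhaustive_solve(problem)
  s <- run_sampler(good, p)
  expect_s3_class(s, "qubo_samples")

  wrong_class <- function(problem, ...) list(bits = matrix(0L, 1, 6))
  expect_error(run_sampler(wrong_class, p), "qubo_samples")

  wrong_len <- function(problem, ...) {
    s <- exhaustive_solve(problem)
    s$bits <- s$bits[, -1, drop = FALSE]
    s
  }
  expect_error(run_sampler(wrong_len, p), "length")

  wrong_energy <- function(problem, ...) {
    s <- exhaustive_solve(problem)
    s$energy <- s$energy + 1
    s
  }
  expect_error(run_sampler(wrong_energy, p), "energies")

  # a plugin backend drives the full pipeline
  fit <- modcom(triangle_graph(), k = 2, penalty = 3, backend = good)
  expect_equal(fit$backend, "plugin")
  expect_equal(fit$modularity,
               brute_force_best_partition(triangle_graph())$modularity,
               tolerance = 1e-9)
})
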