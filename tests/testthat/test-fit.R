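test_that("the pipeline reproduces brute-force optima on toy graphs", {
  cases <- list(list(g = triangle_graph(), k = 2),       # N = 6
                list(g = path4_graph(), k = 3),          # N = 12
                list(g = two_triangles_graph(), k = 3),  # N = 18
                list(g = barbell_graph(), k = 3))        # N = 18
  for (case in cases) {
    oracle <- brute_force_best_partition(case$g)
    fit <- modcom(case$g, k = case$k, backend = "exhaustive")
    expect_equal(fit$modularity, oracle$modularity, tolerance = 1e-9)
    expect_lte(fit$n_communities, case$k)
  }
})

test_that("fit objects are internally consistent and reproducible", {
  g <- zachary()
  fit <- modcom(g, k = 4, num_reads = 100, sweeps = 500, seed = 3)
  # reported Q re-derives exactly from the reported membership
  B <- modularity_matrix(g)
  expect_equal(modularity_score(B, fit$membership), fit$modularity)
  expect_identical(fit$membership, canonicalize_partition(fit$membership) |>
                     stats::setNames(g$nodes))
  expect_equal(fit$n_communities, length(unique(fit$membership)))
  expect_equal(fit$n_vars, 34 * 4)
  expect_equal(fit$penalty, rep(5, 34))  # benchmark's recommended magnitude

  fit2 <- modcom(g, k = 4, num_reads = 100, sweeps = 500, seed = 3)
  expect_identical(fit2$membership, fit$membership)
  expect_equal(fit2$modularity, fit$modularity)

  expect_output(print(fit), "modularity maximization")
  expect_output(print(summary(fit)), "community sizes")
  expect_type(community_members(fit), "list")
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_silent(plot(fit))
})

test_that("k defaults to min(n, k_max) and empty slots are legal", {
  g <- two_triangles_graph()
  fit <- modcom(g, backend = "exhaustive", penalty = 3, k_max = 3)
  expect_equal(fit$k, 3)
  expect_equal(fit$n_communities, 2)  # one slot stays empty
  expect_equal(fit$modularity, 0.5, tolerance = 1e-9)
})

test_that("thresholding provenance flows through the fit", {
  g <- zachary()
  fit <- modcom(g, k = 4, threshold = 0.06, num_reads = 100, sweeps = 500,
                seed = 2)
  expect_equal(fit$retained_pairs, 334L)
  expect_equal(fit$threshold, 0.06)
  # Q is still evaluated on the unthresholded matrix
  expect_equal(modularity_score(modularity_matrix(g), fit$membership),
               fit$modularity)
})

test_that("best modularity is non-decreasing in k under the exact solver", {
  g <- path4_graph()
  tab <- sweep_k(g, k_values = 1:3, backend = "exhaustive", penalty = 2)
  expect_s3_class(tab, "modcom_sweep")
  expect_true(all(diff(tab$modularity) >= -1e-12))
  expect_equal(tab$modularity[1], 0)        # k = 1 is the trivial partition
  expect_equal(tab$n_communities[1], 1)

  tt <- sweep_k(two_triangles_graph(), k_values = 1:3, backend = "exhaustive",
                penalty = 3)
  expect_equal(tt$modularity, c(0, 0.5, 0.5), tolerance = 1e-9)  # plateau
  expect_equal(tt$n_communities, c(1, 2, 2))
})

test_that("threshold scans handle the degenerate all-zero regime", {
  g <- two_triangles_graph()
  B <- modularity_matrix(g)
  tmax <- max(abs(B$B[upper.tri(B$B)]))
  tab <- threshold_scan(g, thresholds = c(0, tmax + 1), k = 3, penalty = 3,
                        num_reads = 50, sweeps = 200, seed = 1)
  expect_s3_class(tab, "modcom_scan")
  expect_equal(tab$retained_pairs[2], 0L)
  expect_equal(tab$modularity[1], 0.5, tolerance = 1e-9)
  # beyond max|B| the QUBO is penalty-only; any feasible state is returned
  # and scored on the original B, so the row still carries a valid Q
  expect_true(is.finite(tab$modularity[2]))
})

test_that("repair mode recovers a usable partition from a weak penalty", {
  pp <- planted_partition(c(6, 6), 0.9, 0.05, seed = 4)
  fit <- modcom(pp$graph, k = 4, penalty = 0.05, num_reads = 50, sweeps = 500,
                seed = 4, repair_infeasible = TRUE)
  expect_gte(fit$modularity, 0.2)
  expect_equal(length(fit$membership), 12)
})

test_that("the command-line front end produces parseable detect output", {
  skip_if_not_installed("optparse")
  skip_if_not_installed("jsonlite")
  cli <- system.file("scripts", "modcom-cli.R", package = "modcom")
  edge <- system.file("extdata", "zachary.edgelist", package = "modcom")
  out <- file.path(withr::local_tempdir(), "zachary")
  rscript <- file.path(R.home("bin"), "Rscript")
  res <- suppressWarnings(system2(
    rscript, c(cli, "detect", edge, "--k", "4", "--penalty", "5",
               "--num-reads", "200", "--sweeps", "1000", "--seed", "7",
               "--quiet", "--out", out),
    stdout = TRUE, stderr = TRUE,
    env = paste0("R_LIBS=", paste(.libPaths(), collapse = ":"))))
  expect_true(file.exists(paste0(out, ".json")))
  expect_true(file.exists(paste0(out, ".tsv")))
  js <- jsonlite::fromJSON(paste0(out, ".json"))
  expect_equal(js$graph$n, 34)
  expect_gte(js$modularity, 0.35)
  tsv <- utils::read.delim(paste0(out, ".tsv"))
  expect_equal(nrow(tsv), 34)
  expect_setequal(names(tsv), c("node", "community"))
})
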