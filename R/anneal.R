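#' Annealing schedule
#'
#' Describes a geometric inverse-temperature ladder for the simulated
#' annealer: `sweeps` full passes over the variables, with the inverse
#' temperature interpolated geometrically from `beta_range[1]` (hot) to
#' `beta_range[2]` (cold).
#'
#' @param sweeps number of sweeps (>= 1); each sweep visits every variable
#'   once in sequential order.
#' @param beta_range length-2 positive increasing vector `(beta_start,
#'   beta_end)`, or `NULL` (default) to auto-scale from the problem's
#'   coefficients at sampling time (see [default_beta_range()]).
#' @return An object of class `anneal_schedule`.
#' @export
anneal_schedule <- function(sweeps = 1000, beta_range = NULL) {
  sweeps <- as.integer(sweeps)[1L]
  if (is.na(sweeps) || sweeps < 1L) stop("sweeps must be >= 1", call. = FALSE)
  if (!is.null(beta_range)) {
    beta_range <- as.numeric(beta_range)
    if (length(beta_range) != 2L || any(!is.finite(beta_range)) ||
        beta_range[1L] <= 0 || beta_range[2L] <= beta_range[1L]) {
      stop("beta_range must satisfy 0 < beta_start < beta_end", call. = FALSE)
    }
  }
  structure(list(sweeps = sweeps, beta_range = beta_range,
                 interpolation = "geometric"),
            class = "anneal_schedule")
}

#' Default inverse-temperature range for a QUBO
#'
#' The hot end accepts the worst possible uphill single-bit flip with
#' probability 1/2: `beta_start = log(2) / max_v (|linear_v| + sum_u |q_uv|)`.
#' The cold end accepts the smallest resolvable uphill move with probability
#' 1/100: `beta_end = log(100) / min nonzero |coefficient|`. This mirrors the
#' usual auto-scaling heuristic of production annealing samplers.
#'
#' @param problem a [build_qubo()] problem.
#' @return `c(beta_start, beta_end)`.
#' @export
default_beta_range <- function(problem) {
  stopifnot(inherits(problem, "qubo_problem"))
  absmax <- abs(problem$linear)
  qa <- abs(problem$quad$value)
  if (length(qa)) {
    rs <- numeric(problem$n_vars)
    agg <- tapply(c(qa, qa), c(problem$quad$i, problem$quad$j), sum)
    rs[as.integer(names(agg))] <- agg
    absmax <- absmax + rs
  }
  hot <- max(absmax, 1e-12)
  coefs <- c(abs(problem$linear), qa)
  coefs <- coefs[coefs > 0]
  cold <- if (length(coefs)) min(coefs) else 1
  c(log(2) / hot, log(100) / cold)
}

.beta_ladder <- function(schedule, problem) {
  br <- schedule$beta_range
  if (is.null(br)) br <- default_beta_range(problem)
  if (schedule$sweeps == 1L) return(br[2L])
  exp(seq(log(br[1L]), log(br[2L]), length.out = schedule$sweeps))
}

.make_samples <- function(bits, energy, meta) {
  o <- order(energy)
  bits <- bits[o, , drop = FALSE]
  energy <- energy[o]
  dup <- duplicated(bits)
  if (any(dup)) {
    key <- apply(bits, 1L, paste0, collapse = "")
    first <- !dup
    n_occ <- as.vector(table(factor(key, levels = unique(key))))
    bits <- bits[first, , drop = FALSE]
    energy <- energy[first]
  } else {
    n_occ <- rep(1L, length(energy))
  }
  structure(c(list(bits = bits, energy = energy, n_occ = n_occ), meta),
            class = "qubo_samples")
}

#' @export
print.qubo_samples <- function(x, ...) {
  cat(sprintf("QUBO samples: %d distinct states from %d reads (%s)\n",
              nrow(x$bits), sum(x$n_occ), x$sampler))
  cat(sprintf("  energy: best %.6g, worst %.6g\n",
              x$energy[1L], x$energy[length(x$energy)]))
  invisible(x)
}

#' Sample a QUBO by simulated annealing
#'
#' Runs `num_reads` independent single-spin-flip Metropolis anneals, each
#' starting from a uniform random bitstring and following the schedule's
#' geometric inverse-temperature ladder, visiting variables in sequential
#' order within a sweep. Each read reports the lowest-energy one-hot-feasible
#' state it visited during the anneal (or its lowest-energy state overall if
#' it never touched a feasible one): the chain passes through its best
#' configurations while barrier crossings are still accepted and can drift off
#' them before freezing. Fully deterministic for a fixed
#' `(problem, num_reads, schedule, seed)`.
#'
#' @param problem a [build_qubo()] problem.
#' @param num_reads number of independent anneals (>= 1).
#' @param schedule an [anneal_schedule()].
#' @param seed integer seed; `NULL` draws one from R's RNG.
#' @return An object of class `qubo_samples`: distinct sampled bitstrings
#'   (`bits`, one row each, sorted by ascending `energy`) with occurrence
#'   counts `n_occ` and sampler metadata.
#' @export
simulated_anneal <- function(problem, num_reads = 1000,
                             schedule = anneal_schedule(), seed = NULL) {
  stopifnot(inherits(problem, "qubo_problem"),
            inherits(schedule, "anneal_schedule"))
  num_reads <- as.integer(num_reads)[1L]
  if (is.na(num_reads) || num_reads < 1L) {
    stop("num_reads must be >= 1", call. = FALSE)
  }
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  seed <- as.integer(seed)[1L]
  betas <- .beta_ladder(schedule, problem)
  csr <- .qubo_csr(problem)
  # one decorrelated sub-seed per read; all randomness flows from `seed`
  read_seeds <- bitwXor(abs(seed), seq_len(num_reads) * 69069L)
  # feasible-state preference only applies to one-hot encoded problems
  # (those built from a modularity matrix); generic QUBOs track the plain
  # lowest-energy state
  onehot_n <- if (!is.null(problem$B)) problem$n else 0L
  res <- sa_anneal_cpp(problem$n_vars, onehot_n, problem$linear, csr$ptr,
                       csr$idx, csr$val, betas, num_reads,
                       as.numeric(read_seeds))
  .make_samples(res$bits, res$energy + problem$offset,
                list(sampler = "simulated_annealing", num_reads = num_reads,
                     sweeps = schedule$sweeps,
                     beta_range = range(betas), seed = seed))
}

#' Solve a QUBO exactly by exhaustive enumeration
#'
#' Enumerates all `2^N` assignments by Gray code with incremental energy
#' updates. A test oracle and exact solver for tiny problems; refuses more
#' than 22 variables.
#'
#' @param problem a [build_qubo()] problem with `n_vars <= 22`.
#' @param tol energy tolerance for membership in the ground-state set.
#' @param max_states cap on the number of returned (near-)ground states.
#' @return A `qubo_samples` object holding the full ground-state set (all
#'   assignments within `tol` of the exact minimum).
#' @export
exhaustive_solve <- function(problem, tol = 1e-9, max_states = 10000) {
  stopifnot(inherits(problem, "qubo_problem"))
  if (problem$n_vars > 22L) {
    stop("exhaustive_solve refuses problems with more than 22 variables (got ",
         problem$n_vars, ")", call. = FALSE)
  }
  csr <- .qubo_csr(problem)
  res <- exhaustive_cpp(problem$n_vars, problem$linear, csr$ptr, csr$idx,
                        csr$val, max(tol, 1e-7), as.integer(max_states))
  keep <- res$energy <= min(res$energy) + tol
  .make_samples(res$bits[keep, , drop = FALSE], res$energy[keep] + problem$offset,
                list(sampler = "exhaustive", num_reads = sum(keep),
                     sweeps = NA_integer_, beta_range = c(NA_real_, NA_real_),
                     seed = NA_integer_))
}

#' Run a pluggable QUBO sampler and validate its output
#'
#' Any function taking a `qubo_problem` (plus `...`) and returning a
#' `qubo_samples` object may serve as a backend — e.g. an adapter around an
#' external quantum or hybrid solver. This wrapper enforces the contract:
#' correct class, bitstring length `n_vars`, 0/1 entries, and energies
#' consistent with [qubo_energy()].
#'
#' @param sampler a function `(problem, ...) -> qubo_samples`.
#' @param problem a [build_qubo()] problem.
#' @param ... passed through to the sampler.
#' @return The validated `qubo_samples`.
#' @export
run_sampler <- function(sampler, problem, ...) {
  stopifnot(is.function(sampler), inherits(problem, "qubo_problem"))
  samples <- sampler(problem, ...)
  if (!inherits(samples, "qubo_samples")) {
    stop("sampler contract violation: result is not a 'qubo_samples' object",
         call. = FALSE)
  }
  if (ncol(samples$bits) != problem$n_vars) {
    stop("sampler contract violation: bitstrings have length ",
         ncol(samples$bits), " but the problem has ", problem$n_vars,
         " variables", call. = FALSE)
  }
  if (!all(samples$bits %in% c(0L, 1L))) {
    stop("sampler contract violation: non-binary entries in bitstrings",
         call. = FALSE)
  }
  check <- vapply(seq_len(nrow(samples$bits)), function(r)
    qubo_energy(problem, samples$bits[r, ]), 0)
  if (any(abs(check - samples$energy) > 1e-6)) {
    stop("sampler contract violation: reported energies disagree with the ",
         "problem's energy function", call. = FALSE)
  }
  samples
}
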