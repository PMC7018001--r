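#' Safe default one-hot penalty magnitude
#'
#' Returns `1 + beta * max_i sum_j |B_ij|`. Flipping any single bit changes the
#' modularity part of the objective by at most the beta-scaled absolute row sum
#' of B, so a penalty exceeding that bound guarantees every strict move toward
#' one-hot feasibility lowers the energy: the global minimizer is feasible.
#' Hand-tuned (smaller) magnitudes can work better in practice because they
#' keep the penalty from swamping the modularity scale.
#'
#' @param B a [modularity_matrix()] (use the thresholded matrix if that is
#'   what the QUBO is built from).
#' @param beta modularity weight.
#' @return A positive scalar penalty magnitude.
#' @export
default_penalty <- function(B, beta = 1) {
  stopifnot(inherits(B, "modularity_matrix"))
  1 + beta * max(rowSums(abs(B$B)))
}

#' Build the k-concurrent one-hot community-detection QUBO
#'
#' Encodes "assign each of n nodes to one of at most k communities" over
#' `N = k * n` binary variables `x[i,j]` (1 iff node i is in community j),
#' column-stacked so variable `(i, j)` has index `i + (j - 1) * n`. The
#' maximization objective \eqn{X^T(\beta \mathbf{B} + B_\Gamma)X - 2\Gamma^T X}
#' — block-diagonal modularity coupling within each community block plus a
#' quadratic one-hot penalty on each logical super-node — is stored negated,
#' as a minimization QUBO with linear terms on the diagonal:
#' within block j, variables i < i' couple with `-2 beta B[i,i']`; variable
#' `(i,j)` has linear term `-beta B[i,i] - penalty[i]`; the k variables of
#' super-node i couple pairwise with `+2 penalty[i]`. For any feasible one-hot
#' assignment, `energy = -beta * 2m * Q - sum(penalty)` where Q is the
#' modularity of the decoded partition evaluated on the matrix the problem was
#' built from.
#'
#' @param B a [modularity_matrix()], possibly thresholded; its provenance is
#'   carried on the problem.
#' @param k number of concurrent communities (k >= 1). `k = n` is always
#'   sufficient; smaller k shrinks the problem.
#' @param penalty positive one-hot penalty magnitude, scalar or per-node
#'   vector; `NULL` (default) uses [default_penalty()]. This is the absolute
#'   value of the (negative) relaxation coefficient of the penalty term.
#' @param beta positive weight of the modularity term (default 1).
#' @return An object of class `qubo_problem`: `n_vars`, `linear` (length N),
#'   `quad` (list of parallel vectors `i`, `j`, `value`, i < j), `offset`
#'   (0; reserved for shifted energy conventions), and metadata
#'   `n`, `k`, `beta`, `penalty`, `B`.
#' @examples
#' B <- modularity_matrix(mod_graph(c("a","b","c"), c("b","c","a")))
#' q <- build_qubo(B, k = 2)
#' q$n_vars  # 6
#' @export
build_qubo <- function(B, k, penalty = NULL, beta = 1) {
  stopifnot(inherits(B, "modularity_matrix"))
  k <- as.integer(k)[1L]
  if (is.na(k) || k < 1L) stop("k must be a positive integer", call. = FALSE)
  beta <- as.numeric(beta)[1L]
  if (is.na(beta) || beta <= 0) stop("beta must be positive", call. = FALSE)
  if (is.null(penalty)) penalty <- default_penalty(B, beta)
  penalty <- rep_len(as.numeric(penalty), B$n)
  if (anyNA(penalty) || any(penalty <= 0)) {
    stop("penalty magnitude must be positive (the one-hot constraint is ",
         "unenforced otherwise)", call. = FALSE)
  }
  n <- B$n
  N <- n * k
  Bm <- B$B

  # modularity couplings, replicated across the k diagonal blocks
  ut <- which(upper.tri(Bm) & Bm != 0, arr.ind = TRUE)
  blk <- rep((seq_len(k) - 1L) * n, each = nrow(ut))
  qi <- rep(ut[, 1L], k) + blk
  qj <- rep(ut[, 2L], k) + blk
  qv <- rep(-2 * beta * Bm[ut], k)

  # one-hot penalty: couple the k variables of each super-node pairwise
  if (k > 1L) {
    jl <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
    pi_ <- rep(seq_len(n), each = nrow(jl)) + n * rep(jl[, 1L] - 1L, n)
    pj_ <- rep(seq_len(n), each = nrow(jl)) + n * rep(jl[, 2L] - 1L, n)
    pv <- 2 * rep(penalty, each = nrow(jl))
    qi <- c(qi, pi_); qj <- c(qj, pj_); qv <- c(qv, pv)
  }

  linear <- rep(-beta * diag(Bm) - penalty, k)

  structure(
    list(n_vars = N, linear = linear,
         quad = list(i = as.integer(qi), j = as.integer(qj), value = qv),
         offset = 0, n = n, k = k, beta = beta, penalty = penalty, B = B),
    class = "qubo_problem"
  )
}

#' @export
print.qubo_problem <- function(x, ...) {
  cat(sprintf(
    "QUBO: %d variables (n = %d nodes x k = %d), %d couplings, beta = %g\n",
    x$n_vars, x$n, x$k, length(x$quad$value), x$beta))
  cat(sprintf("  one-hot penalty magnitude: %s\n",
              paste(format(unique(x$penalty), digits = 4), collapse = ", ")))
  if (!is.na(x$B$retained_pairs)) {
    cat(sprintf("  built from B thresholded at %g (%d retained pairs)\n",
                x$B$threshold, x$B$retained_pairs))
  }
  invisible(x)
}

#' Energy of an assignment
#'
#' Evaluates \eqn{\sum_{u \le v} q_{uv} b_u b_v + \mathrm{offset}} for one
#' binary assignment of a [build_qubo()] problem (lower is better).
#'
#' @param problem a `qubo_problem`.
#' @param bits 0/1 vector of length `problem$n_vars`.
#' @return The scalar energy.
#' @export
qubo_energy <- function(problem, bits) {
  stopifnot(inherits(problem, "qubo_problem"))
  bits <- as.numeric(bits)
  if (length(bits) != problem$n_vars) {
    stop("assignment length ", length(bits), " != ", problem$n_vars,
         call. = FALSE)
  }
  if (!all(bits %in% c(0, 1))) stop("assignment must be 0/1", call. = FALSE)
  sum(problem$linear * bits) +
    sum(problem$quad$value * bits[problem$quad$i] * bits[problem$quad$j]) +
    problem$offset
}

# symmetric adjacency (CSR, 0-based) of the QUBO coupling graph, for the
# compiled kernels
.qubo_csr <- function(problem) {
  N <- problem$n_vars
  i <- c(problem$quad$i, problem$quad$j)
  j <- c(problem$quad$j, problem$quad$i)
  v <- c(problem$quad$value, problem$quad$value)
  o <- order(i, j)
  i <- i[o]; j <- j[o]; v <- v[o]
  ptr <- c(0L, cumsum(tabulate(i, nbins = N)))
  list(ptr = as.integer(ptr), idx = as.integer(j - 1L), val = v)
}
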