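#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// xorshift64* with a splitmix64 seed scrambler: fast, seedable per read,
// independent of R's RNG stream so results are reproducible across platforms.
static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}
static inline uint64_t xorshift64s(uint64_t &s) {
  s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
  return s * 0x2545F4914F6CDD1DULL;
}
static inline double runif01(uint64_t &s) {
  return (xorshift64s(s) >> 11) * (1.0 / 9007199254740992.0); // [0, 1)
}

// exact energy from scratch: sum_v b_v (linear_v + 0.5 * sum_u q_uv b_u)
static double full_energy(const std::vector<int> &b, const NumericVector &linear,
                          const IntegerVector &ptr, const IntegerVector &idx,
                          const NumericVector &val) {
  long double e = 0.0L;
  const int N = (int)b.size();
  for (int v = 0; v < N; ++v) {
    if (!b[v]) continue;
    long double f = linear[v];
    for (int p = ptr[v]; p < ptr[v + 1]; ++p)
      if (b[idx[p]]) f += 0.5 * val[p];
    e += f;
  }
  return (double)e;
}

// Simulated annealing on a QUBO in symmetric-CSR form. Each read is an
// independent single-spin-flip Metropolis anneal from a uniform random
// bitstring, visiting variables in sequential order within each sweep and
// following the inverse-temperature ladder `betas` (one value per sweep).
// Each read reports the lowest-energy ONE-HOT-FEASIBLE state it visited
// (tracked in O(1) per flip through per-super-node set-bit counts, with
// super-node membership v mod n under column stacking), not the final state:
// the single-flip chain traverses its best configurations in the mid-schedule
// window where one-hot barrier crossings are still accepted, and may drift off
// them before freezing. A read that never visits a feasible state reports its
// lowest-energy state overall, which decoding then flags.
// [[Rcpp::export]]
List sa_anneal_cpp(int n_vars, int n_nodes, NumericVector linear,
                   IntegerVector ptr, IntegerVector idx, NumericVector val,
                   NumericVector betas, int num_reads, NumericVector seeds) {
  const int N = n_vars, S = betas.size();
  // super-node of variable v is v % n; n_nodes = 0 disables one-hot tracking
  const int n = n_nodes > 0 ? n_nodes : 1;
  const bool onehot = n_nodes > 0;
  IntegerMatrix bits_out(num_reads, N);
  NumericVector energies(num_reads);
  std::vector<int> b(N), best_b(N), cnt(n);
  std::vector<double> f(N); // local field: linear + sum of active couplings

  // raw local copies: keep the Metropolis loop free of R object access
  const double *lin = REAL(linear);
  const double *bet = REAL(betas);
  const double *qv = REAL(val);
  const int *qp = INTEGER(ptr);
  const int *qi = INTEGER(idx);

  for (int r = 0; r < num_reads; ++r) {
    uint64_t rng = splitmix64((uint64_t)seeds[r]);
    for (int v = 0; v < N; ++v) b[v] = (int)(xorshift64s(rng) & 1ULL);
    double E = 0.0;
    std::fill(cnt.begin(), cnt.end(), 0);
    for (int v = 0; v < N; ++v) {
      double fv = lin[v];
      for (int p = qp[v]; p < qp[v + 1]; ++p)
        if (b[qi[p]]) fv += qv[p];
      f[v] = fv;
      if (b[v]) { E += lin[v] + 0.5 * (fv - lin[v]); ++cnt[v % n]; }
    }
    int violated = 0;
    if (onehot) for (int i = 0; i < n; ++i) violated += (cnt[i] != 1);
    double bestE = E;
    bool best_feasible = (violated == 0);
    best_b = b;
    for (int s = 0; s < S; ++s) {
      const double beta = bet[s];
      for (int v = 0; v < N; ++v) {
        const double dE = b[v] ? -f[v] : f[v];
        bool accept;
        if (dE <= 0.0) {
          accept = true;
        } else {
          const double bdE = beta * dE;
          accept = (bdE < 50.0) && (runif01(rng) < std::exp(-bdE));
        }
        if (accept) {
          const double sgn = b[v] ? -1.0 : 1.0;
          if (onehot) {
            const int i = v % n;
            violated -= (cnt[i] != 1);
            cnt[i] += b[v] ? -1 : 1;
            violated += (cnt[i] != 1);
          }
          b[v] = 1 - b[v];
          E += dE;
          for (int p = qp[v]; p < qp[v + 1]; ++p) f[qi[p]] += sgn * qv[p];
          const bool feas = (violated == 0);
          if ((feas && !best_feasible) ||
              (feas == best_feasible && E < bestE - 1e-12)) {
            bestE = E; best_b = b; best_feasible = feas;
          }
        }
      }
    }
    for (int v = 0; v < N; ++v) bits_out(r, v) = best_b[v];
    energies[r] = full_energy(best_b, linear, ptr, idx, val);
  }
  return List::create(_["bits"] = bits_out, _["energy"] = energies);
}

// Exhaustive enumeration of all 2^N assignments by Gray code (one bit flip
// per step, incremental energy). Returns the exact minimum and every
// assignment within `tol` of it (capped).
// [[Rcpp::export]]
List exhaustive_cpp(int n_vars, NumericVector linear, IntegerVector ptr,
                    IntegerVector idx, NumericVector val, double tol,
                    int max_states) {
  const int N = n_vars;
  if (N > 22) stop("exhaustive enumeration capped at 22 variables");
  const uint64_t total = 1ULL << N;
  std::vector<int> b(N, 0);
  std::vector<double> f(linear.begin(), linear.end());
  long double E = 0.0L;
  double minE = 0.0; // energy of the all-zeros state

  // pass 1: find the minimum
  for (uint64_t t = 1; t < total; ++t) {
    const int v = __builtin_ctzll(t);
    const double dE = b[v] ? -f[v] : f[v];
    E += dE;
    const double sgn = b[v] ? -1.0 : 1.0;
    b[v] = 1 - b[v];
    for (int p = ptr[v]; p < ptr[v + 1]; ++p) f[idx[p]] += sgn * val[p];
    if ((double)E < minE) minE = (double)E;
  }

  // pass 2: collect states within tol of the minimum, re-scoring exactly
  std::fill(b.begin(), b.end(), 0);
  std::copy(linear.begin(), linear.end(), f.begin());
  E = 0.0L;
  std::vector<uint32_t> codes;
  if (minE >= -tol) codes.push_back(0u);
  uint32_t code = 0u;
  for (uint64_t t = 1; t < total; ++t) {
    const int v = __builtin_ctzll(t);
    const double dE = b[v] ? -f[v] : f[v];
    E += dE;
    const double sgn = b[v] ? -1.0 : 1.0;
    b[v] = 1 - b[v];
    code ^= (1u << v);
    for (int p = ptr[v]; p < ptr[v + 1]; ++p) f[idx[p]] += sgn * val[p];
    if ((double)E <= minE + tol && (int)codes.size() < max_states)
      codes.push_back(code);
  }

  const int ns = (int)codes.size();
  IntegerMatrix bits_out(ns, N);
  NumericVector energies(ns);
  std::vector<int> bb(N);
  for (int s = 0; s < ns; ++s) {
    for (int v = 0; v < N; ++v) bb[v] = (int)((codes[s] >> v) & 1u);
    energies[s] = full_energy(bb, linear, ptr, idx, val);
    for (int v = 0; v < N; ++v) bits_out(s, v) = bb[v];
  }
  return List::create(_["bits"] = bits_out, _["energy"] = energies,
                      _["min_energy"] = minE);
}
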