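#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Full-precision Hamiltonian of the current region state.
// Interior cliques are counted once (u > t); boundary incidences once per
// (interior cell, adjacent river cell) pair.
static long double region_energy(const std::vector<double> &w,
                                 const IntegerMatrix &nbr,
                                 const IntegerVector &n_river,
                                 const NumericVector &sb,
                                 const NumericVector &ssb,
                                 const NumericVector &d2,
                                 double g) {
  const int m = (int)w.size();
  long double e = 0.0L;
  for (int t = 0; t < m; ++t) {
    for (int k = 0; k < 4; ++k) {
      int u = nbr(t, k);
      if (u > t) {
        long double diff = (long double)w[t] - (long double)w[u];
        e += diff * diff;
      }
    }
    // sum over adjacent river cells s of (w_t - b_s)^2
    e += (long double)n_river[t] * (long double)w[t] * (long double)w[t]
       - 2.0L * (long double)sb[t] * (long double)w[t]
       + (long double)ssb[t];
    e += (long double)g * (long double)d2[t] * (long double)w[t];
  }
  return e;
}

// Single-site Metropolis chain over one region.
//
// Cells are given in sweep order (the layered ordering); one sweep proposes
// a uniform value on [0, K] at every cell once.  A proposal with negative
// energy increment is always taken; otherwise it is taken with probability
// exp(-dH/T) against an independent uniform draw, which is generated only
// when needed.  Uses R's RNG, so set.seed() on the R side makes the chain
// reproducible.
//
// nbr:     m x 4 matrix of in-region neighbour indices in sweep order
//          (0-based; -1 = no neighbour in that slot)
// n_river: number of adjacent river cells per cell
// sb/ssb:  sum and sum of squares of boundary values on those river cells
// d2:      squared river distance per cell
// [[Rcpp::export(name = ".chain_cpp")]]
List chain_cpp(NumericVector init, IntegerMatrix nbr, IntegerVector n_river,
               NumericVector sb, NumericVector ssb, NumericVector d2,
               double K, double g, double T, int n_sweeps, int tail_sweeps,
               bool record_states) {
  const int m = init.size();
  std::vector<double> w(init.begin(), init.end());
  std::vector<long double> tail_sum(m, 0.0L);
  NumericVector energy(n_sweeps);
  NumericMatrix states;
  if (record_states) states = NumericMatrix(m, n_sweeps);

  long long accepted = 0;
  const long long proposals = (long long)m * (long long)n_sweeps;
  const int tail_start = n_sweeps - tail_sweeps; // sweeps are 0-based here

  for (int s = 0; s < n_sweeps; ++s) {
    for (int t = 0; t < m; ++t) {
      const double cur = w[t];
      const double x = unif_rand() * K; // proposal, uniform on [0, K]
      double dh = 0.0;
      for (int k = 0; k < 4; ++k) {
        int u = nbr(t, k);
        if (u >= 0) {
          double dn = x - w[u], dc = cur - w[u];
          dh += dn * dn - dc * dc;
        }
      }
      dh += n_river[t] * (x * x - cur * cur) - 2.0 * sb[t] * (x - cur);
      dh += g * d2[t] * (x - cur);
      bool take = dh < 0.0;
      if (!take) {
        double y = unif_rand();
        take = y <= std::exp(-dh / T);
      }
      if (take) {
        w[t] = x;
        ++accepted;
      }
    }
    energy[s] = (double)region_energy(w, nbr, n_river, sb, ssb, d2, g);
    if (s >= tail_start)
      for (int t = 0; t < m; ++t) tail_sum[t] += w[t];
    if (record_states)
      for (int t = 0; t < m; ++t) states(t, s) = w[t];
  }

  NumericVector final_state(m), tail_avg(m);
  for (int t = 0; t < m; ++t) {
    final_state[t] = w[t];
    tail_avg[t] = (double)(tail_sum[t] / (long double)tail_sweeps);
  }

  List out = List::create(
      _["final_state"] = final_state, _["tail_average"] = tail_avg,
      _["energy_trace"] = energy,
      _["acceptance_rate"] = (double)accepted / (double)proposals);
  if (record_states) out["states"] = states;
  return out;
}
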