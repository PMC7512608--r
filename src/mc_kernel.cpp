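#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Logit-rule (Glauber heat-bath) sweeps on the L x L periodic square lattice.
//
// Strategies are 0-based internally; the R wrappers use 1..n. One Monte Carlo
// step (MCS) = N single-site update attempts at independently drawn random
// sites, so each player gets one revision opportunity on average. The new
// strategy is drawn from the full logit distribution over all n candidates
// (current strategy included in the normalisation), which for a symmetric
// payoff matrix satisfies detailed balance with respect to exp(U/K).
//
// For small n the logit distribution depends on the neighborhood only through
// the 4 neighbor strategies, so cumulative probabilities are tabulated over
// all n^4 neighbor configurations once per (A, K); each site update then
// costs one table gather and one uniform draw.

static inline int draw_from_cum(const double *cum, int n, double u) {
  for (int s = 0; s < n - 1; ++s)
    if (u <= cum[s]) return s;
  return n - 1;
}

// [[Rcpp::export]]
IntegerMatrix cpp_mc_sweeps(IntegerMatrix sites, NumericMatrix A, double K,
                            int sweeps) {
  const int L = sites.nrow();
  if (sites.ncol() != L) stop("lattice must be square");
  const int n = A.nrow();
  const int N = L * L;

  IntegerMatrix out = clone(sites);
  int *s = INTEGER(out);

  // periodic neighbor offsets, linear column-major indexing p = r + L*c
  std::vector<int> up(N), dn(N), lf(N), rt(N);
  for (int c = 0; c < L; ++c) {
    for (int r = 0; r < L; ++r) {
      int p = r + L * c;
      up[p] = (r == 0 ? L - 1 : r - 1) + L * c;
      dn[p] = (r == L - 1 ? 0 : r + 1) + L * c;
      lf[p] = r + L * (c == 0 ? L - 1 : c - 1);
      rt[p] = r + L * (c == L - 1 ? 0 : c + 1);
    }
  }

  const double *a = REAL(A);
  RNGScope scope;

  bool use_table = (double)n * n * n * n * n <= 4e6;
  std::vector<double> tab;
  if (use_table) {
    // cumulative logit probabilities for every ordered neighbor configuration
    int ncfg = n * n * n * n;
    tab.resize((size_t)ncfg * n);
    std::vector<double> w(n);
    for (int j1 = 0; j1 < n; ++j1)
      for (int j2 = 0; j2 < n; ++j2)
        for (int j3 = 0; j3 < n; ++j3)
          for (int j4 = 0; j4 < n; ++j4) {
            int cfg = ((j1 * n + j2) * n + j3) * n + j4;
            double mx = -INFINITY;
            for (int k = 0; k < n; ++k) {
              double u = a[k + n * j1] + a[k + n * j2] + a[k + n * j3] +
                         a[k + n * j4];
              w[k] = u / K;
              if (w[k] > mx) mx = w[k];
            }
            double tot = 0.0;
            for (int k = 0; k < n; ++k) { w[k] = std::exp(w[k] - mx); tot += w[k]; }
            double acc = 0.0;
            for (int k = 0; k < n; ++k) {
              acc += w[k] / tot;
              tab[(size_t)cfg * n + k] = acc;
            }
          }
  }

  std::vector<double> w(n);
  for (int t = 0; t < sweeps; ++t) {
    for (int i = 0; i < N; ++i) {
      int p = (int)(unif_rand() * N);
      if (p >= N) p = N - 1;
      int j1 = s[up[p]] - 1, j2 = s[dn[p]] - 1, j3 = s[lf[p]] - 1,
          j4 = s[rt[p]] - 1;
      double u2 = unif_rand();
      int snew;
      if (use_table) {
        int cfg = ((j1 * n + j2) * n + j3) * n + j4;
        snew = draw_from_cum(&tab[(size_t)cfg * n], n, u2);
      } else {
        double mx = -INFINITY;
        for (int k = 0; k < n; ++k) {
          double u = a[k + n * j1] + a[k + n * j2] + a[k + n * j3] +
                     a[k + n * j4];
          w[k] = u / K;
          if (w[k] > mx) mx = w[k];
        }
        double tot = 0.0;
        for (int k = 0; k < n; ++k) { w[k] = std::exp(w[k] - mx); tot += w[k]; }
        double acc = 0.0, uu = u2 * tot;
        snew = n - 1;
        for (int k = 0; k < n; ++k) {
          acc += w[k];
          if (uu <= acc) { snew = k; break; }
        }
      }
      s[p] = snew + 1;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_strategy_counts(IntegerMatrix sites, int n) {
  NumericVector cnt(n);
  const int *s = INTEGER(sites);
  int N = sites.nrow() * sites.ncol();
  for (int i = 0; i < N; ++i) cnt[s[i] - 1] += 1.0;
  return cnt;
}

// Sum of the pair potential over the 2N undirected nearest-neighbor edges.
// [[Rcpp::export]]
double cpp_total_potential(IntegerMatrix sites, NumericMatrix V) {
  const int L = sites.nrow();
  const int n = V.nrow();
  const int *s = INTEGER(sites);
  const double *v = REAL(V);
  double U = 0.0;
  for (int c = 0; c < L; ++c) {
    for (int r = 0; r < L; ++r) {
      int p = r + L * c;
      int dn = (r == L - 1 ? 0 : r + 1) + L * c;
      int rt = r + L * (c == L - 1 ? 0 : c + 1);
      U += v[(s[p] - 1) + n * (s[dn] - 1)];
      U += v[(s[p] - 1) + n * (s[rt] - 1)];
    }
  }
  return U;
}

// Sweeps with in-kernel moment accumulation of a built-in order parameter:
// op = 1: rho_1 - rho_2 (Ising pair), op = 2: (n max_i rho_i - 1)/(n - 1)
// (Potts). Strategy counts are maintained incrementally, so sampling every
// MCS costs O(n) per step. Returns sums of |m|, m^2, m^4 over t_sample MCS
// and the final lattice.
// [[Rcpp::export]]
List cpp_mc_moments(IntegerMatrix sites, NumericMatrix A, double K,
                    int t_relax, int t_sample, int op) {
  const int L = sites.nrow();
  const int n = A.nrow();
  const int N = L * L;
  IntegerMatrix cur = clone(sites);
  int *s = INTEGER(cur);

  std::vector<int> up(N), dn(N), lf(N), rt(N);
  for (int c = 0; c < L; ++c) {
    for (int r = 0; r < L; ++r) {
      int p = r + L * c;
      up[p] = (r == 0 ? L - 1 : r - 1) + L * c;
      dn[p] = (r == L - 1 ? 0 : r + 1) + L * c;
      lf[p] = r + L * (c == 0 ? L - 1 : c - 1);
      rt[p] = r + L * (c == L - 1 ? 0 : c + 1);
    }
  }
  const double *a = REAL(A);
  RNGScope scope;

  int ncfg = n * n * n * n;
  std::vector<double> tab((size_t)ncfg * n);
  {
    std::vector<double> w(n);
    for (int cfg = 0; cfg < ncfg; ++cfg) {
      int j4 = cfg % n, j3 = (cfg / n) % n, j2 = (cfg / (n * n)) % n,
          j1 = cfg / (n * n * n);
      double mx = -INFINITY;
      for (int k = 0; k < n; ++k) {
        double u = a[k + n * j1] + a[k + n * j2] + a[k + n * j3] +
                   a[k + n * j4];
        w[k] = u / K;
        if (w[k] > mx) mx = w[k];
      }
      double tot = 0.0;
      for (int k = 0; k < n; ++k) { w[k] = std::exp(w[k] - mx); tot += w[k]; }
      double acc = 0.0;
      for (int k = 0; k < n; ++k) {
        acc += w[k] / tot;
        tab[(size_t)cfg * n + k] = acc;
      }
    }
  }

  std::vector<long> cnt(n, 0);
  for (int i = 0; i < N; ++i) cnt[s[i] - 1]++;

  double s_abs = 0.0, s_m2 = 0.0, s_m4 = 0.0;
  for (int t = 0; t < t_relax + t_sample; ++t) {
    for (int i = 0; i < N; ++i) {
      int p = (int)(unif_rand() * N);
      if (p >= N) p = N - 1;
      int j1 = s[up[p]] - 1, j2 = s[dn[p]] - 1, j3 = s[lf[p]] - 1,
          j4 = s[rt[p]] - 1;
      int cfg = ((j1 * n + j2) * n + j3) * n + j4;
      int snew = draw_from_cum(&tab[(size_t)cfg * n], n, unif_rand());
      cnt[s[p] - 1]--;
      cnt[snew]++;
      s[p] = snew + 1;
    }
    if (t >= t_relax) {
      double m;
      if (op == 1) {
        m = (double)(cnt[0] - cnt[1]) / N;
      } else {
        long mx = cnt[0];
        for (int k = 1; k < n; ++k) if (cnt[k] > mx) mx = cnt[k];
        m = (n * (double)mx / N - 1.0) / (n - 1.0);
      }
      double am = std::fabs(m);
      s_abs += am; s_m2 += m * m; s_m4 += m * m * m * m;
    }
  }
  return List::create(_["sites"] = cur, _["sum_abs"] = s_abs,
                      _["sum_m2"] = s_m2, _["sum_m4"] = s_m4,
                      _["n_samples"] = t_sample);
}
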