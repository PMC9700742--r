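#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Elementary symmetric polynomials of the membership columns.
//
// cache(d, k) = sum over all d-subsets S of {1..N} of prod_{j in S} u_jk,
// for d = 0..D. Row d of the returned matrix is degree d; cache(0, k) = 1.
// Built by the standard one-node-at-a-time recurrence in O(N D K).
static void build_cache(const NumericMatrix& u, int D, NumericMatrix& C) {
  const int N = u.nrow(), K = u.ncol();
  std::fill(C.begin(), C.end(), 0.0);
  for (int k = 0; k < K; ++k) {
    C(0, k) = 1.0;
    for (int j = 0; j < N; ++j) {
      const double ujk = u(j, k);
      const int top = std::min(D, j + 1);
      for (int d = top; d >= 1; --d)
        C(d, k) += ujk * C(d - 1, k);
    }
  }
}

// [[Rcpp::export(name = ".espCacheCpp")]]
NumericMatrix espCacheCpp(NumericMatrix u, int D) {
  NumericMatrix C(D + 1, u.ncol());
  build_cache(u, D, C);
  return C;
}

// Poisson rate lambda_e = sum_k w_{d_e,k} prod_{i in e} u_ik for each
// listed hyperedge. `edges` holds 1-based node ids; w row d-1 is size d+1
// (rows are sizes 2..D).
// [[Rcpp::export(name = ".ratesCpp")]]
NumericVector ratesCpp(List edges, IntegerVector sizes,
                       NumericMatrix u, NumericMatrix w) {
  const int E = edges.size(), K = u.ncol();
  NumericVector lam(E);
  for (int e = 0; e < E; ++e) {
    IntegerVector mem = edges[e];
    const int d = sizes[e];
    double s = 0.0;
    for (int k = 0; k < K; ++k) {
      double p = w(d - 2, k);
      if (p == 0.0) continue;
      for (int m = 0; m < mem.size(); ++m) p *= u(mem[m] - 1, k);
      s += p;
    }
    lam[e] = s;
  }
  return lam;
}

// Variational E-step: rho_ek proportional to w_{d_e,k} prod_{i in e} u_ik,
// rows normalized to 1. Rows with identically zero rate are set uniform and
// flagged degenerate.
// [[Rcpp::export(name = ".eStepCpp")]]
List eStepCpp(List edges, IntegerVector sizes,
              NumericMatrix u, NumericMatrix w) {
  const int E = edges.size(), K = u.ncol();
  NumericMatrix rho(E, K);
  LogicalVector degen(E);
  std::vector<double> lam(K);
  for (int e = 0; e < E; ++e) {
    IntegerVector mem = edges[e];
    const int d = sizes[e];
    double s = 0.0;
    for (int k = 0; k < K; ++k) {
      double p = w(d - 2, k);
      for (int m = 0; m < mem.size() && p != 0.0; ++m) p *= u(mem[m] - 1, k);
      lam[k] = p;
      s += p;
    }
    if (s > 0.0) {
      for (int k = 0; k < K; ++k) rho(e, k) = lam[k] / s;
    } else {
      degen[e] = true;
      for (int k = 0; k < K; ++k) rho(e, k) = 1.0 / K;
    }
  }
  return List::create(_["rho"] = rho, _["degenerate"] = degen);
}

// Multiplicative membership update, one Gauss-Seidel sweep over nodes.
//
// For node i, community k:
//   numerator   = sum over observed incident hyperedges of A_e * rho_ek
//   denominator = sum_{d=2..D} w_dk * C_k^{(-i)}(d-1)  [+ gamma]
// with the leave-one-out values obtained by deflating the global cache:
//   C^{(-i)}(d) = C(d) - u_ik * C^{(-i)}(d-1).
// After a node's row is written, the cache is refolded with the new values
// (C(d) = C^{(-i)}(d) + u_new * C^{(-i)}(d-1)), so later nodes see the
// current memberships. Deflation can cancel catastrophically: negatives
// within -1e-12 are clipped to 0, larger ones trigger a full rebuild.
// [[Rcpp::export(name = ".updateUCpp")]]
List updateUCpp(List edges, NumericVector A, IntegerVector sizes,
                NumericMatrix u0, NumericMatrix w, NumericMatrix rho,
                double gamma, bool normalized) {
  const int N = u0.nrow(), K = u0.ncol(), E = edges.size();
  const int D = w.nrow() + 1;
  NumericMatrix u = clone(u0);

  // Numerators are independent of u; accumulate once for the sweep.
  NumericMatrix num(N, K);
  for (int e = 0; e < E; ++e) {
    IntegerVector mem = edges[e];
    for (int m = 0; m < mem.size(); ++m) {
      const int i = mem[m] - 1;
      for (int k = 0; k < K; ++k) num(i, k) += A[e] * rho(e, k);
    }
  }

  NumericMatrix C(D + 1, K);
  build_cache(u, D, C);

  std::vector<double> Cm((size_t)(D + 1) * K);  // leave-one-out, per k
  std::vector<double> newrow(K);
  std::vector<int> ill;

  for (int i = 0; i < N; ++i) {
    for (int attempt = 0; attempt < 2; ++attempt) {
      bool bad = false;
      for (int k = 0; k < K && !bad; ++k) {
        double* cm = &Cm[(size_t)k * (D + 1)];
        cm[0] = 1.0;
        for (int d = 1; d <= D; ++d) {
          double v = C(d, k) - u(i, k) * cm[d - 1];
          if (v < 0.0) {
            if (v >= -1e-12) v = 0.0;
            else { bad = true; break; }
          }
          cm[d] = v;
        }
      }
      if (!bad) break;
      build_cache(u, D, C);  // refresh and retry; clip on second pass
      if (attempt == 1) {
        for (int k = 0; k < K; ++k) {
          double* cm = &Cm[(size_t)k * (D + 1)];
          for (int d = 0; d <= D; ++d) if (cm[d] < 0.0) cm[d] = 0.0;
        }
      }
    }

    for (int k = 0; k < K; ++k) {
      const double* cm = &Cm[(size_t)k * (D + 1)];
      double den = gamma;
      for (int d = 2; d <= D; ++d) den += w(d - 2, k) * cm[d - 1];
      const double nm = num(i, k);
      double val;
      if (nm == 0.0) {
        val = 0.0;
      } else if (den == 0.0) {
        val = u(i, k);  // ill-conditioned: keep for this sweep
        ill.push_back(i + 1);
      } else {
        val = nm / den;
      }
      newrow[k] = val;
    }

    if (normalized) {
      double s = 0.0;
      for (int k = 0; k < K; ++k) s += newrow[k];
      if (s > 0.0) for (int k = 0; k < K; ++k) newrow[k] /= s;
      else         for (int k = 0; k < K; ++k) newrow[k] = 1.0 / K;
    }

    for (int k = 0; k < K; ++k) {
      const double* cm = &Cm[(size_t)k * (D + 1)];
      u(i, k) = newrow[k];
      C(0, k) = 1.0;
      for (int d = 1; d <= D; ++d) C(d, k) = cm[d] + newrow[k] * cm[d - 1];
    }
  }

  return List::create(_["u"] = u, _["cache"] = C,
                      _["illConditioned"] = wrap(ill));
}

// Affinity update: w_dk = (sum over observed size-d hyperedges of
// A_e rho_ek) / C_k(d). Sizes with no observed hyperedge, or with a zero
// denominator, get w_dk = 0.
// [[Rcpp::export(name = ".updateWCpp")]]
NumericMatrix updateWCpp(NumericVector A, IntegerVector sizes,
                         NumericMatrix rho, NumericMatrix cache) {
  const int K = rho.ncol(), D = cache.nrow() - 1, E = A.size();
  NumericMatrix w(D - 1, K), num(D - 1, K);
  for (int e = 0; e < E; ++e)
    for (int k = 0; k < K; ++k)
      num(sizes[e] - 2, k) += A[e] * rho(e, k);
  for (int d = 2; d <= D; ++d)
    for (int k = 0; k < K; ++k) {
      const double den = cache(d, k), nm = num(d - 2, k);
      w(d - 2, k) = (den > 0.0 && nm > 0.0) ? nm / den : 0.0;
    }
  return w;
}

// First (penalty) term of the log-likelihood: sum_{e in Omega} lambda_e
// = sum_{d=2..D} sum_k w_dk C_k(d), via the cache.
// [[Rcpp::export(name = ".omegaTermCpp")]]
double omegaTermCpp(NumericMatrix w, NumericMatrix cache) {
  const int D = cache.nrow() - 1, K = cache.ncol();
  double s = 0.0;
  for (int d = 2; d <= D; ++d)
    for (int k = 0; k < K; ++k) s += w(d - 2, k) * cache(d, k);
  return s;
}
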