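#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// 1-based upper-triangle dyad index for a < b on n individuals
static inline int dyad_index(int a, int b, int n) {
  return (a - 1) * n - a * (a - 1) / 2 + (b - a);
}

// Sequential within-scan double-edge-swap chain for the association
// permutation test. Each swap picks two edges of the same scan and rewires
// them, preserving every individual's within-scan degree and the scan's
// edge count. Because presence patterns are untouched, each dyad's HWI
// denominator is fixed; only the joint-association counts x change, so the
// chain tracks x alone and reports the coefficient of variation of x/den
// over dyads with positive denominator after every `swaps_per_perm`
// attempted swaps.
//
// edges: rows (scan, a, b), all 1-based. den: per-dyad HWI denominators in
// upper-triangle order. Uses R's RNG (seed with set.seed in R).
// [[Rcpp::export]]
List assoc_perm_chain(IntegerMatrix edges, int n_scans, int n_ind,
                      NumericVector den, int n_perm, double swaps_per_perm,
                      double burn_in, bool return_edges) {
  const int m = edges.nrow();
  const int nd = n_ind * (n_ind - 1) / 2;
  std::vector<int> esc(m), ea(m), eb(m);
  std::vector< std::vector<int> > scan_edges(n_scans);
  std::vector< std::vector<char> > adj(n_scans);
  std::vector<double> x(nd, 0.0);

  for (int e = 0; e < m; ++e) {
    int s = edges(e, 0) - 1, a = edges(e, 1), b = edges(e, 2);
    if (a > b) std::swap(a, b);
    esc[e] = s; ea[e] = a; eb[e] = b;
    scan_edges[s].push_back(e);
    if (adj[s].empty()) adj[s].assign((size_t)n_ind * n_ind, 0);
    adj[s][(size_t)(a - 1) * n_ind + (b - 1)] = 1;
    x[dyad_index(a, b, n_ind) - 1] += 1.0;
  }
  std::vector<int> valid;
  for (int k = 0; k < nd; ++k) if (den[k] > 0) valid.push_back(k);

  NumericVector cvs(n_perm);

  for (long long step = -(long long)burn_in, rec = 0; rec < n_perm; ++step) {
    if (m >= 2) {
      int e1 = (int)(unif_rand() * m); if (e1 >= m) e1 = m - 1;
      int s = esc[e1];
      int ns = (int)scan_edges[s].size();
      if (ns >= 2) {
        int e2 = scan_edges[s][(int)(unif_rand() * ns) % ns];
        if (e2 != e1) {
          int a = ea[e1], b = eb[e1], c = ea[e2], d = eb[e2];
          if (a != c && a != d && b != c && b != d) {
            int na1, nb1, na2, nb2;
            if (unif_rand() < 0.5) { na1 = a; nb1 = d; na2 = c; nb2 = b; }
            else                   { na1 = a; nb1 = c; na2 = b; nb2 = d; }
            if (na1 > nb1) std::swap(na1, nb1);
            if (na2 > nb2) std::swap(na2, nb2);
            if (!adj[s][(size_t)(na1 - 1) * n_ind + (nb1 - 1)] &&
                !adj[s][(size_t)(na2 - 1) * n_ind + (nb2 - 1)]) {
              adj[s][(size_t)(a - 1) * n_ind + (b - 1)] = 0;
              adj[s][(size_t)(c - 1) * n_ind + (d - 1)] = 0;
              adj[s][(size_t)(na1 - 1) * n_ind + (nb1 - 1)] = 1;
              adj[s][(size_t)(na2 - 1) * n_ind + (nb2 - 1)] = 1;
              x[dyad_index(a, b, n_ind) - 1] -= 1.0;
              x[dyad_index(c, d, n_ind) - 1] -= 1.0;
              x[dyad_index(na1, nb1, n_ind) - 1] += 1.0;
              x[dyad_index(na2, nb2, n_ind) - 1] += 1.0;
              ea[e1] = na1; eb[e1] = nb1; ea[e2] = na2; eb[e2] = nb2;
            }
          }
        }
      }
    }
    if (step >= 0 && ((step + 1) % (long long)swaps_per_perm == 0)) {
      double sum = 0.0, nv = (double)valid.size();
      for (size_t vi = 0; vi < valid.size(); ++vi) sum += x[valid[vi]] / den[valid[vi]];
      double mean = sum / nv;
      if (mean <= 0 || nv < 2) {
        cvs[rec++] = NA_REAL;
      } else {
        double ss = 0.0;
        for (size_t vi = 0; vi < valid.size(); ++vi) {
          double v = x[valid[vi]] / den[valid[vi]] - mean;
          ss += v * v;
        }
        cvs[rec++] = std::sqrt(ss / (nv - 1)) / mean;
      }
      if ((rec & 255) == 0) Rcpp::checkUserInterrupt();
    }
  }

  List out = List::create(_["cv"] = cvs);
  if (return_edges) {
    IntegerMatrix fin(m, 3);
    for (int e = 0; e < m; ++e) { fin(e, 0) = esc[e] + 1; fin(e, 1) = ea[e]; fin(e, 2) = eb[e]; }
    out["edges"] = fin;
  }
  return out;
}
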