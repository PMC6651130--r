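#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

// Hairpin-restricted nearest-neighbor MFE folding.
//
// The structure space is limited to stem-loops: a single terminal loop
// closed by a chain of nested pairs separated by stacks, bulges or internal
// loops.  Multibranch loops are excluded -- only stem-loop precursors
// matter for miRNA hairpin validation.  Energies (kcal/mol at 37C) come
// from the stacking matrix and loop penalty vectors passed from R.

static inline int pair_index(char a, char b) {
  // order must match the R-side table: AU UA GC CG GU UG
  if (a == 'A' && b == 'U') return 0;
  if (a == 'U' && b == 'A') return 1;
  if (a == 'G' && b == 'C') return 2;
  if (a == 'C' && b == 'G') return 3;
  if (a == 'G' && b == 'U') return 4;
  if (a == 'U' && b == 'G') return 5;
  return -1;
}

// [[Rcpp::export]]
List fold_hairpin_cpp(std::string seq, NumericMatrix stack6,
                      NumericVector hairpin_pen, NumericVector bulge_pen,
                      NumericVector internal_pen, int min_loop,
                      int max_interior) {
  const int n = (int)seq.size();
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> E((size_t)n * n, INF);
  std::vector<int> cp((size_t)n * n, -1), cq((size_t)n * n, -1);
  auto at = [&](int i, int j) { return (size_t)(i - 1) * n + (j - 1); };

  std::vector<int> pidx((size_t)n * n, -1);
  for (int i = 1; i <= n; ++i)
    for (int j = i + 1; j <= n; ++j)
      pidx[at(i, j)] = pair_index(seq[i - 1], seq[j - 1]);

  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 1; i + len - 1 <= n; ++i) {
      int j = i + len - 1;
      int pij = pidx[at(i, j)];
      if (pij < 0) continue;
      // close a terminal (hairpin) loop of size j-i-1 >= min_loop
      double best = hairpin_pen[(j - i - 1) - 1];
      int bp = -1, bq = -1;
      // extend inward via stack / bulge / internal loop to pair (p, q)
      int l1max = std::min(max_interior, j - i - 2 - min_loop);
      for (int l1 = 0; l1 <= l1max; ++l1) {
        int p = i + 1 + l1;
        int l2max = std::min(max_interior - l1, j - p - 2 - min_loop);
        for (int l2 = 0; l2 <= l2max; ++l2) {
          int q = j - 1 - l2;
          if (q - p - 1 < min_loop) continue;
          size_t kpq = at(p, q);
          if (E[kpq] == INF) continue;
          double cost;
          if (l1 == 0 && l2 == 0) cost = stack6(pij, pidx[kpq]);
          else if (l1 == 0 || l2 == 0) cost = bulge_pen[l1 + l2 - 1];
          else cost = internal_pen[l1 + l2 - 1];
          double cand = cost + E[kpq];
          if (cand < best - 1e-12) { best = cand; bp = p; bq = q; }
        }
      }
      E[at(i, j)] = best;
      cp[at(i, j)] = bp;
      cq[at(i, j)] = bq;
    }
  }

  // global MFE: best closed structure, or the open chain at 0
  double mfe = 0.0;
  int bi = -1, bj = -1;
  for (int i = 1; i <= n; ++i)
    for (int j = i + min_loop + 1; j <= n; ++j) {
      double e = E[at(i, j)];
      if (e < mfe - 1e-12) { mfe = e; bi = i; bj = j; }
    }

  std::string db(n, '.');
  std::vector<int> pi, pj;
  if (bi > 0) {
    int i = bi, j = bj;
    while (i > 0) {
      db[i - 1] = '('; db[j - 1] = ')';
      pi.push_back(i); pj.push_back(j);
      int p = cp[at(i, j)], q = cq[at(i, j)];
      i = p; j = q;
      if (p < 0) break;
    }
  }
  return List::create(_["structure"] = db, _["dG"] = (bi > 0 ? mfe : 0.0),
                      _["pair_i"] = wrap(pi), _["pair_j"] = wrap(pj));
}
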