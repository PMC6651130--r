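#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

// Plant miRNA-target duplex scoring.
//
// The miRNA (5'->3') pairs antiparallel with the target site, so the DP
// aligns the miRNA against the reversed site with a complementarity pairing
// rule.  Penalties: mismatch 1.0, G:U wobble 0.5, single-nucleotide bulge on
// either strand 1.0; every penalty is multiplied by core_mult when it falls
// at miRNA positions core_start..core_end (counted from the miRNA 5' end).
// A target-side bulge between miRNA positions i and i+1 is attributed to
// position i+1 (the next miRNA base to be consumed).

static inline int pair_class(char a, char b) {
  // a = miRNA base, b = target base; 0 = Watson-Crick, 1 = G:U wobble, 2 = MM
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A') ||
      (a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return 0;
  if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return 1;
  return 2;
}

// [[Rcpp::export]]
List duplex_dp_cpp(std::string mirna, std::string site, int max_bulges,
                   double mismatch, double wobble, double bulge_pen,
                   double core_mult, int core_start, int core_end) {
  const int L = (int)mirna.size();
  const int S = (int)site.size();
  const double INF = std::numeric_limits<double>::infinity();
  if (std::abs(L - S) > max_bulges)
    return List::create(_["score"] = R_PosInf, _["ops"] = "");

  // reversed site: r[j] faces mirna position j when bulge-free
  std::string r(site.rbegin(), site.rend());

  const int B = max_bulges;
  // state (i, j, b): mirna[1..i] vs r[1..j] with b bulges used
  const int NI = L + 1, NJ = S + 1, NB = B + 1;
  std::vector<double> sc((size_t)NI * NJ * NB, INF);
  std::vector<int> nb((size_t)NI * NJ * NB, 0);      // bulges (tie-break 1)
  std::vector<int> nw((size_t)NI * NJ * NB, 0);      // WC pairs (tie-break 2)
  std::vector<signed char> ch((size_t)NI * NJ * NB, -1); // 0 pair,1 tbulge,2 mbulge
  auto idx = [&](int i, int j, int b) { return ((size_t)i * NJ + j) * NB + b; };

  auto core = [&](int pos) {
    return (pos >= core_start && pos <= core_end) ? core_mult : 1.0;
  };
  // better-than under (score, bulges, -wc) lexicographic order
  auto better = [&](double s1, int b1, int w1, double s2, int b2, int w2) {
    if (s1 < s2 - 1e-12) return true;
    if (s1 > s2 + 1e-12) return false;
    if (b1 != b2) return b1 < b2;
    return w1 > w2;
  };

  sc[idx(0, 0, 0)] = 0.0;
  for (int i = 0; i <= L; ++i) {
    for (int j = 0; j <= S; ++j) {
      if (std::abs(i - j) > B) continue;
      for (int b = 0; b <= B; ++b) {
        double cur = sc[idx(i, j, b)];
        if (cur == INF) continue;
        int cb = nb[idx(i, j, b)], cw = nw[idx(i, j, b)];
        // pair mirna[i+1] with r[j+1]
        if (i < L && j < S) {
          int pc = pair_class(mirna[i], r[j]);
          double pen = (pc == 0) ? 0.0 : (pc == 1 ? wobble : mismatch);
          pen *= core(i + 1);
          size_t k = idx(i + 1, j + 1, b);
          double ns = cur + pen;
          int nwv = cw + (pc == 0 ? 1 : 0);
          if (ch[k] == -1 || better(ns, cb, nwv, sc[k], nb[k], nw[k])) {
            sc[k] = ns; nb[k] = cb; nw[k] = nwv; ch[k] = 0;
          }
        }
        if (b < B) {
          // miRNA-side bulge: mirna[i+1] unpaired
          if (i < L && std::abs((i + 1) - j) <= B) {
            double pen = bulge_pen * core(i + 1);
            size_t k = idx(i + 1, j, b + 1);
            double ns = cur + pen;
            if (ch[k] == -1 || better(ns, cb + 1, cw, sc[k], nb[k], nw[k])) {
              sc[k] = ns; nb[k] = cb + 1; nw[k] = cw; ch[k] = 2;
            }
          }
          // target-side bulge: r[j+1] unpaired, attributed to position i+1
          if (j < S && std::abs(i - (j + 1)) <= B) {
            double pen = bulge_pen * core(std::min(i + 1, L));
            size_t k = idx(i, j + 1, b + 1);
            double ns = cur + pen;
            if (ch[k] == -1 || better(ns, cb + 1, cw, sc[k], nb[k], nw[k])) {
              sc[k] = ns; nb[k] = cb + 1; nw[k] = cw; ch[k] = 1;
            }
          }
        }
      }
    }
  }

  double best = INF; int bestb = -1, bw = 0, bb = 0;
  for (int b = 0; b <= B; ++b) {
    size_t k = idx(L, S, b);
    if (sc[k] < INF &&
        (bestb < 0 || better(sc[k], nb[k], nw[k], best, bb, bw))) {
      best = sc[k]; bestb = b; bb = nb[k]; bw = nw[k];
    }
  }
  if (bestb < 0)
    return List::create(_["score"] = R_PosInf, _["ops"] = "");

  // traceback: ops from miRNA 5' end; W/G/M pair classes, x miRNA bulge,
  // o target bulge (extra target base)
  std::string ops;
  {
    int i = L, j = S, b = bestb;
    while (i > 0 || j > 0) {
      signed char c = ch[idx(i, j, b)];
      if (c == 0) {
        int pc = pair_class(mirna[i - 1], r[j - 1]);
        ops.push_back(pc == 0 ? 'W' : (pc == 1 ? 'G' : 'M'));
        --i; --j;
      } else if (c == 2) { ops.push_back('x'); --i; --b; }
      else               { ops.push_back('o'); --j; --b; }
    }
    std::reverse(ops.begin(), ops.end());
  }
  return List::create(_["score"] = best, _["ops"] = ops,
                      _["bulges"] = bestb, _["wc"] = bw);
}

// score-only banded DP over one window (no traceback, no tie-breaks)
static double duplex_score_only(const std::string& m, const std::string& rwin,
                                int B, double mismatch, double wobble,
                                double bulge_pen, double core_mult,
                                int core_start, int core_end) {
  const int L = (int)m.size(), S = (int)rwin.size();
  const double INF = std::numeric_limits<double>::infinity();
  if (std::abs(L - S) > B) return INF;
  const int NJ = S + 1, NB = B + 1;
  std::vector<double> cur((size_t)NJ * NB, INF), nxt((size_t)NJ * NB, INF);
  auto core = [&](int pos) {
    return (pos >= core_start && pos <= core_end) ? core_mult : 1.0;
  };
  cur[0] = 0.0;
  for (int j = 1; j <= std::min(S, B); ++j)
    for (int b = j; b <= B; ++b)
      cur[(size_t)j * NB + b] = j * bulge_pen * core(1);
  for (int i = 1; i <= L; ++i) {
    std::fill(nxt.begin(), nxt.end(), INF);
    for (int j = std::max(0, i - B); j <= std::min(S, i + B); ++j) {
      for (int b = 0; b <= B; ++b) {
        double best = INF;
        if (j > 0) {
          double prev = cur[(size_t)(j - 1) * NB + b];
          if (prev < INF) {
            int pc = pair_class(m[i - 1], rwin[j - 1]);
            double pen = (pc == 0) ? 0.0 : (pc == 1 ? wobble : mismatch);
            best = prev + pen * core(i);
          }
        }
        if (b > 0) {
          double viaM = cur[(size_t)j * NB + (b - 1)];
          if (viaM < INF)
            best = std::min(best, viaM + bulge_pen * core(i));
          double viaT = (j > 0) ? nxt[(size_t)(j - 1) * NB + (b - 1)] : INF;
          if (viaT < INF)
            best = std::min(best, viaT + bulge_pen * core(std::min(i + 1, L)));
        }
        nxt[(size_t)j * NB + b] = best;
      }
    }
    std::swap(cur, nxt);
  }
  double best = INF;
  for (int b = 0; b <= B; ++b)
    best = std::min(best, cur[(size_t)S * NB + b]);
  return best;
}

// [[Rcpp::export]]
DataFrame duplex_scan_cpp(std::string mirna, std::string transcript,
                          int max_bulges, double cutoff, bool inclusive,
                          double mismatch, double wobble, double bulge_pen,
                          double core_mult, int core_start, int core_end) {
  const int L = (int)mirna.size(), n = (int)transcript.size();
  std::vector<int> starts, lens;
  std::vector<double> scores;
  // prefix count of N for fast window exclusion
  std::vector<int> npre(n + 1, 0);
  for (int i = 0; i < n; ++i)
    npre[i + 1] = npre[i] + (transcript[i] == 'N' ? 1 : 0);
  for (int v = L - max_bulges; v <= L + max_bulges; ++v) {
    if (v < 1 || v > n) continue;
    for (int st = 1; st + v - 1 <= n; ++st) {
      if (npre[st + v - 1] - npre[st - 1] > 0) continue;
      std::string win = transcript.substr(st - 1, v);
      std::string rwin(win.rbegin(), win.rend());
      double sc = duplex_score_only(mirna, rwin, max_bulges, mismatch,
                                    wobble, bulge_pen, core_mult,
                                    core_start, core_end);
      bool keep = inclusive ? (sc <= cutoff) : (sc < cutoff);
      if (keep && sc < std::numeric_limits<double>::infinity()) {
        starts.push_back(st); lens.push_back(v); scores.push_back(sc);
      }
    }
  }
  return DataFrame::create(_["site_start"] = starts, _["site_len"] = lens,
                           _["score"] = scores);
}
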