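#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Scoring variants: 0 = basic match count, 1 = IC-weighted,
// 2 = pairwise score (PS), 3 = IC-weighted pairwise score (ICPS).
//
// The PS/ICPS triple sum (over s = 1..K, i = 1..|w|-s, k = 1..s) is
// evaluated in closed form: the term for the pair (i, i+k) is repeated once
// for every s with k <= s <= min(K, |w|-i), so its weight is
// min(K, |w|-i) - k + 1. Equality with the literal triple loop is pinned by
// tests against an independent oracle.

static double overlap_score(const int* t, int lt, const int* cons, int lc,
                            const IntegerMatrix& mt, int variant, int K,
                            const NumericVector& col_ic,
                            const NumericMatrix& pair_ic,
                            int off, int min_overlap) {
  int c1 = std::max(1, off);
  int c2 = std::min(lc, off + lt - 1);
  int L = c2 - c1 + 1;
  if (L < min_overlap) return R_NegInf;

  std::vector<unsigned char> m(L);
  for (int i = 0; i < L; ++i) {
    int c = c1 + i;               // consensus column, 1-based
    int p = c - off;              // 0-based site index
    m[i] = (unsigned char) mt(cons[c - 1], t[p]);
  }

  double acc = 0.0;
  if (variant == 0) {
    for (int i = 0; i < L; ++i) acc += m[i];
  } else if (variant == 1) {
    for (int i = 0; i < L; ++i)
      if (m[i]) acc += col_ic[c1 - 1 + i];
  } else {
    int Keff = (K < 0) ? (L - 1) : std::min(K, L - 1);
    for (int k = 1; k <= Keff; ++k) {
      for (int i = 1; i + k <= L; ++i) {          // i is 1-based within w
        if (m[i - 1] && m[i - 1 + k]) {
          int wmax = std::min(Keff, L - i);
          int wt = wmax - k + 1;
          if (wt <= 0) continue;
          if (variant == 2) {
            acc += 2.0 * wt;
          } else {
            acc += 2.0 * wt * pair_ic(c1 - 1 + (i - 1), c1 - 1 + (i - 1) + k);
          }
        }
      }
    }
  }
  return acc;
}

// [[Rcpp::export]]
double scan_cpp(IntegerVector t, IntegerVector cons, IntegerMatrix mt,
                int variant, int K, NumericVector col_ic,
                NumericMatrix pair_ic, int min_overlap) {
  int lt = t.size(), lc = cons.size();
  double best = R_NegInf;
  for (int off = 2 - lt; off <= lc; ++off) {
    double s = overlap_score(t.begin(), lt, cons.begin(), lc, mt, variant, K,
                             col_ic, pair_ic, off, min_overlap);
    if (s > best) best = s;
  }
  return best;
}

// [[Rcpp::export]]
NumericVector scan_batch_cpp(List seqs, IntegerVector cons, IntegerMatrix mt,
                             int variant, int K, NumericVector col_ic,
                             NumericMatrix pair_ic, int min_overlap) {
  int n = seqs.size(), lc = cons.size();
  NumericVector out(n);
  for (int q = 0; q < n; ++q) {
    IntegerVector t = seqs[q];
    int lt = t.size();
    double best = R_NegInf;
    for (int off = 2 - lt; off <= lc; ++off) {
      double s = overlap_score(t.begin(), lt, cons.begin(), lc, mt, variant,
                               K, col_ic, pair_ic, off, min_overlap);
      if (s > best) best = s;
    }
    out[q] = best;
  }
  return out;
}
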