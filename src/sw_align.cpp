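#include <Rcpp.h>
using namespace Rcpp;

// Token-level Smith-Waterman local alignment with +1 match, -1
// mismatch, -1 gap.  Tokens arrive as integer codes (factor levels
// assigned in R); slot symbols are ordinary codes, so a slot matches
// only the identical slot.  Traceback prefers diagonal over up over
// left and starts from the maximal cell with smallest (i, j).

// [[Rcpp::export]]
List sw_align_int(IntegerVector a, IntegerVector b) {
  const int n = a.size(), m = b.size();
  std::vector<int> H((n + 1) * (m + 1), 0);
  auto idx = [m](int i, int j) { return i * (m + 1) + j; };
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int diag = H[idx(i - 1, j - 1)] + (a[i - 1] == b[j - 1] ? 1 : -1);
      int up = H[idx(i - 1, j)] - 1;
      int left = H[idx(i, j - 1)] - 1;
      int v = diag;
      if (up > v) v = up;
      if (left > v) v = left;
      if (v < 0) v = 0;
      H[idx(i, j)] = v;
      if (v > best) { best = v; bi = i; bj = j; }
    }
  }
  // traceback
  std::vector<int> ai, bjv;  // aligned pairs, 1-based or NA (gap)
  int i = bi, j = bj;
  while (i > 0 && j > 0 && H[idx(i, j)] > 0) {
    int h = H[idx(i, j)];
    int diag = H[idx(i - 1, j - 1)] + (a[i - 1] == b[j - 1] ? 1 : -1);
    if (h == diag) {
      ai.push_back(i); bjv.push_back(j);
      --i; --j;
    } else if (h == H[idx(i - 1, j)] - 1) {
      ai.push_back(i); bjv.push_back(NA_INTEGER);
      --i;
    } else {
      ai.push_back(NA_INTEGER); bjv.push_back(j);
      --j;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bjv.begin(), bjv.end());
  IntegerVector pa(ai.begin(), ai.end()), pb(bjv.begin(), bjv.end());
  int a_lo = 0, a_hi = 0, b_lo = 0, b_hi = 0;
  for (size_t k = 0; k < ai.size(); ++k) {
    if (ai[k] != NA_INTEGER) {
      if (a_lo == 0) a_lo = ai[k];
      a_hi = ai[k];
    }
    if (bjv[k] != NA_INTEGER) {
      if (b_lo == 0) b_lo = bjv[k];
      b_hi = bjv[k];
    }
  }
  return List::create(_["score"] = best,
                      _["a_range"] = IntegerVector::create(a_lo, a_hi),
                      _["b_range"] = IntegerVector::create(b_lo, b_hi),
                      _["pairs_a"] = pa, _["pairs_b"] = pb);
}

// Scores of all unordered pairs i < j among a list of integer token
// sequences; returns only pairs scoring >= min_score.
// [[Rcpp::export]]
DataFrame sw_all_pairs_int(List seqs, int min_score) {
  const int n = seqs.size();
  std::vector<std::vector<int>> ss(n);
  for (int i = 0; i < n; ++i) ss[i] = as<std::vector<int>>(seqs[i]);
  std::vector<int> oi, oj, osc;
  std::vector<int> H;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const std::vector<int> &a = ss[i], &b = ss[j];
      const int la = a.size(), lb = b.size();
      H.assign((size_t)(la + 1) * (lb + 1), 0);
      int best = 0;
      for (int p = 1; p <= la; ++p) {
        const int base = p * (lb + 1), prev = (p - 1) * (lb + 1);
        for (int q = 1; q <= lb; ++q) {
          int diag = H[prev + q - 1] + (a[p - 1] == b[q - 1] ? 1 : -1);
          int up = H[prev + q] - 1;
          int left = H[base + q - 1] - 1;
          int v = diag;
          if (up > v) v = up;
          if (left > v) v = left;
          if (v < 0) v = 0;
          H[base + q] = v;
          if (v > best) best = v;
        }
      }
      if (best >= min_score) {
        oi.push_back(i + 1); oj.push_back(j + 1); osc.push_back(best);
      }
    }
  }
  return DataFrame::create(_["i"] = oi, _["j"] = oj, _["score"] = osc);
}
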