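#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Global (end-to-end) pairwise alignment with affine gap costs, Gotoh
// three-state DP. A gap of length L costs gap_open + L * gap_extend
// (the Biostrings convention). Sequences arrive as 0-based integer codes
// into the substitution matrix.

static const double NEG = -1e15;

struct GotohBuf {
  std::vector<double> M, X, Y, Mp, Xp, Yp;
  void resize(int m) {
    M.resize(m + 1); X.resize(m + 1); Y.resize(m + 1);
    Mp.resize(m + 1); Xp.resize(m + 1); Yp.resize(m + 1);
  }
};

static double gotoh_score(const int* a, int n, const int* b, int m,
                          const double* sub, int ncode,
                          double go, double ge, GotohBuf& buf) {
  buf.resize(m);
  double* M = buf.M.data();  double* X = buf.X.data();  double* Y = buf.Y.data();
  double* Mp = buf.Mp.data(); double* Xp = buf.Xp.data(); double* Yp = buf.Yp.data();
  Mp[0] = 0.0; Xp[0] = NEG; Yp[0] = NEG;
  for (int j = 1; j <= m; ++j) {
    Mp[j] = NEG; Xp[j] = NEG;
    Yp[j] = -(go + ge * j); // leading gap in a
  }
  for (int i = 1; i <= n; ++i) {
    M[0] = NEG; Y[0] = NEG;
    X[0] = -(go + ge * i); // leading gap in b
    const double* srow = sub + (size_t)a[i - 1]; // column-major: + ncode*b[j]
    for (int j = 1; j <= m; ++j) {
      double s = srow[(size_t)ncode * b[j - 1]];
      double diag = std::max(Mp[j - 1], std::max(Xp[j - 1], Yp[j - 1]));
      M[j] = diag + s;
      X[j] = std::max(Mp[j] - (go + ge),
                      std::max(Xp[j] - ge, Yp[j] - (go + ge)));
      Y[j] = std::max(M[j - 1] - (go + ge),
                      std::max(Y[j - 1] - ge, X[j - 1] - (go + ge)));
    }
    std::swap(buf.M, buf.Mp); std::swap(buf.X, buf.Xp); std::swap(buf.Y, buf.Yp);
    M = buf.M.data(); X = buf.X.data(); Y = buf.Y.data();
    Mp = buf.Mp.data(); Xp = buf.Xp.data(); Yp = buf.Yp.data();
  }
  return std::max(Mp[m], std::max(Xp[m], Yp[m]));
}

// [[Rcpp::export]]
NumericVector cpp_align_scores(List seq_a, List seq_b, NumericMatrix sub,
                               double gap_open, double gap_extend) {
  int n = seq_a.size();
  if (seq_b.size() != n) stop("sequence lists must have equal length");
  NumericVector out(n);
  GotohBuf buf;
  for (int i = 0; i < n; ++i) {
    IntegerVector ai = seq_a[i], bi = seq_b[i];
    out[i] = gotoh_score(ai.begin(), ai.size(), bi.begin(), bi.size(),
                         sub.begin(), sub.nrow(), gap_open, gap_extend, buf);
  }
  return out;
}

// All-pairs alignment distances d(i, j) = min(S(i,i), S(j,j)) - S(i,j)
// among unique sequences, returning only pairs with d <= cutoff.
// Pairs whose length difference exceeds max_len_diff are skipped
// (their forced gap cost already puts them beyond the cutoff).
//
// Fast exact path: when every substitution score satisfies
// s(x, y) <= min(s(x, x), s(y, y)) with positive diagonals (true for
// BLOSUM62 over the 20 standard residues) and 2 * (gap_open +
// gap_extend) > cutoff, any gapped alignment of equal-length sequences
// scores at least 2 * (gap_open + gap_extend) below min(self), so only
// the ungapped diagonal alignment can fall within the cutoff; pairs of
// unequal length are beyond the cutoff whenever
// gap_open + gap_extend * |len diff| > cutoff. Both reductions are
// exact, not approximations; the general Gotoh DP covers every other
// parameter regime.
// [[Rcpp::export]]
DataFrame cpp_distance_edges(List seqs, NumericMatrix sub, double gap_open,
                             double gap_extend, double cutoff,
                             int max_len_diff) {
  int n = seqs.size();
  int ncode = sub.nrow();
  const double* subp = sub.begin();
  std::vector<std::vector<int>> enc(n);
  std::vector<double> self(n);
  std::vector<bool> used(ncode, false);
  GotohBuf buf;
  for (int i = 0; i < n; ++i) {
    IntegerVector v = seqs[i];
    enc[i].assign(v.begin(), v.end());
    for (int c : enc[i]) used[c] = true;
    self[i] = gotoh_score(enc[i].data(), enc[i].size(), enc[i].data(),
                          enc[i].size(), subp, ncode, gap_open, gap_extend, buf);
  }
  bool dominated_diag = true; // s(x,y) <= min diag, diag > 0, over used codes
  for (int x = 0; x < ncode && dominated_diag; ++x) {
    if (!used[x]) continue;
    double dx = subp[(size_t)x + (size_t)ncode * x];
    if (dx <= 0) { dominated_diag = false; break; }
    for (int y = 0; y < ncode; ++y) {
      if (!used[y] || y == x) continue;
      double dy = subp[(size_t)y + (size_t)ncode * y];
      double s = subp[(size_t)x + (size_t)ncode * y];
      if (s > std::min(dx, dy)) { dominated_diag = false; break; }
    }
  }
  bool fast_equal = dominated_diag && 2 * (gap_open + gap_extend) > cutoff;
  // order by length so the inner loop can stop once the length gap is
  // too large (lossless: gap cost alone already exceeds the cutoff)
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int x, int y) {
    return enc[x].size() < enc[y].size();
  });
  std::vector<int> oi, oj;
  std::vector<double> od;
  for (int u = 0; u < n; ++u) {
    if (u % 256 == 0) Rcpp::checkUserInterrupt();
    int i = ord[u];
    int li = enc[i].size();
    const int* ai = enc[i].data();
    for (int v = u + 1; v < n; ++v) {
      int j = ord[v];
      int lj = enc[j].size();
      if (lj - li > max_len_diff) break; // sorted by length
      if (lj != li && dominated_diag &&
          gap_open + gap_extend * (lj - li) > cutoff)
        break; // forced gap cost beyond cutoff for this and longer seqs
      double s;
      if (lj == li && fast_equal) {
        s = 0.0;
        const int* bj = enc[j].data();
        for (int k = 0; k < li; ++k)
          s += subp[(size_t)ai[k] + (size_t)ncode * bj[k]];
        // the ungapped score is optimal whenever it is within the
        // cutoff of min(self); otherwise the pair fails either way
      } else {
        s = gotoh_score(ai, li, enc[j].data(), lj, subp, ncode,
                        gap_open, gap_extend, buf);
      }
      double d = std::min(self[i], self[j]) - s;
      if (d <= cutoff) {
        oi.push_back(std::min(i, j) + 1);
        oj.push_back(std::max(i, j) + 1);
        od.push_back(d);
      }
    }
  }
  return DataFrame::create(_["i"] = oi, _["j"] = oj, _["d"] = od);
}
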