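#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap global alignment (Gotoh three-state DP) over "profiles":
// each side is an integer matrix (sequences x columns) of indices into the
// substitution matrix, -1 marking a gap.  A plain sequence is a 1-row
// profile.  Column-vs-column score is the mean substitution score over all
// residue pairs with both members non-gap (0 if no such pair).
//
// Gap cost follows the BLAST convention: a gap of length k costs
// gap_open + k * gap_extend.
//
// Tie-breaking in the traceback is fixed: diagonal (match/mismatch) wins,
// then a gap in the first profile, then a gap in the second.

static inline double col_score(const IntegerMatrix& A, int i,
                               const IntegerMatrix& B, int j,
                               const NumericMatrix& S) {
  double sum = 0.0;
  int cnt = 0;
  for (int r = 0; r < A.nrow(); ++r) {
    int a = A(r, i);
    if (a < 0) continue;
    for (int s = 0; s < B.nrow(); ++s) {
      int b = B(s, j);
      if (b < 0) continue;
      sum += S(a, b);
      ++cnt;
    }
  }
  return cnt ? sum / cnt : 0.0;
}

// [[Rcpp::export]]
List align_profiles_cpp(IntegerMatrix A, IntegerMatrix B, NumericMatrix S,
                        double gap_open, double gap_extend) {
  const int n = A.ncol(), m = B.ncol();
  const double NEG = -1e30;
  const double open1 = gap_open + gap_extend;  // first gapped column

  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  M(0, 0) = 0.0; X(0, 0) = NEG; Y(0, 0) = NEG;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG; Y(i, 0) = NEG;
    X(i, 0) = -(gap_open + gap_extend * i);
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG; X(0, j) = NEG;
    Y(0, j) = -(gap_open + gap_extend * j);
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = col_score(A, i - 1, B, j - 1, S);
      double dm = M(i - 1, j - 1), dx = X(i - 1, j - 1), dy = Y(i - 1, j - 1);
      M(i, j) = s + std::max(dm, std::max(dx, dy));
      X(i, j) = std::max(M(i - 1, j) - open1,
                std::max(X(i - 1, j) - gap_extend, Y(i - 1, j) - open1));
      Y(i, j) = std::max(M(i, j - 1) - open1,
                std::max(Y(i, j - 1) - gap_extend, X(i, j - 1) - open1));
    }
  }

  double best = std::max(M(n, m), std::max(X(n, m), Y(n, m)));
  // state codes: 0 = M (diagonal), 1 = X (gap in B side), 2 = Y (gap in A)
  int state;
  if (M(n, m) >= best) state = 0;
  else if (Y(n, m) >= best) state = 2;
  else state = 1;

  std::vector<int> outA, outB;  // 1-based source column, 0 = gap
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      outA.push_back(i); outB.push_back(j);
      double target = M(i, j) - col_score(A, i - 1, B, j - 1, S);
      --i; --j;
      if (i == 0 && j == 0) break;
      if (M(i, j) >= target - 1e-9) state = 0;
      else if (Y(i, j) >= target - 1e-9) state = 2;
      else state = 1;
    } else if (state == 1) {
      outA.push_back(i); outB.push_back(0);
      double cur = X(i, j);
      --i;
      if (M(i, j) - open1 >= cur - 1e-9) state = 0;
      else if (X(i, j) - gap_extend >= cur - 1e-9) state = 1;
      else state = 2;
    } else {
      outA.push_back(0); outB.push_back(j);
      double cur = Y(i, j);
      --j;
      if (M(i, j) - open1 >= cur - 1e-9) state = 0;
      else if (Y(i, j) - gap_extend >= cur - 1e-9) state = 2;
      else state = 1;
    }
  }
  std::reverse(outA.begin(), outA.end());
  std::reverse(outB.begin(), outB.end());

  return List::create(_["score"] = best,
                      _["a_cols"] = IntegerVector(outA.begin(), outA.end()),
                      _["b_cols"] = IntegerVector(outB.begin(), outB.end()));
}
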