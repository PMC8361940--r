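#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

// Affine-gap global alignment (Gotoh) between two alignment profiles.
//
// A profile is a (K+1) x L count matrix: rows 0..K-1 are the substitution
// matrix alphabet, row K counts gap characters already present in the
// profile.  A single sequence is the one-hot special case, for which the
// column score collapses to the plain substitution score.
//
// Column score between profile columns i and j is the average-of-pairs
// substitution score over the rows of both profiles; a residue paired
// with a gap character already present in the other profile costs
// gap_extend (so residues cannot drift into gap-dominated columns for
// free, which would fragment long insertions), and gap-gap pairs cost
// nothing.  New gaps opened by this alignment
// cost gap_open for the first column and gap_extend for each further
// column (a length-L gap costs open + (L-1)*extend); terminal gaps are
// charged in full (true global alignment).
//
// Traceback is deterministic with tie preference diagonal > up > left,
// where "up" consumes a column of A and "left" a column of B.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export]]
List cpp_profile_align(NumericMatrix cntA, NumericMatrix cntB,
                       NumericMatrix S, double rowsA, double rowsB,
                       double gap_open, double gap_extend) {
  const int K = S.nrow();             // alphabet size (no gap row)
  const int nA = cntA.ncol(), nB = cntB.ncol();
  if (cntA.nrow() != K + 1 || cntB.nrow() != K + 1)
    stop("profile count matrices must have K+1 rows");

  // VA[y + i*K] = sum_x cntA(x,i) * S(x,y)   (gap row contributes 0)
  std::vector<double> VA((size_t)K * nA, 0.0);
  for (int i = 0; i < nA; ++i)
    for (int x = 0; x < K; ++x) {
      double c = cntA(x, i);
      if (c != 0.0)
        for (int y = 0; y < K; ++y) VA[(size_t)i * K + y] += c * S(x, y);
    }
  const double norm = rowsA * rowsB;

  auto colscore = [&](int i, int j) {
    double s = 0.0;
    const double *va = &VA[(size_t)i * K];
    for (int y = 0; y < K; ++y) {
      double c = cntB(y, j);
      if (c != 0.0) s += va[y] * c;
    }
    const double gapA = cntA(K, i), gapB = cntB(K, j);
    s -= gap_extend * (gapA * (rowsB - gapB) + gapB * (rowsA - gapA));
    return s / norm;
  };

  const int W = nB + 1;
  std::vector<double> M((size_t)(nA + 1) * W, NEG_INF);
  std::vector<double> X((size_t)(nA + 1) * W, NEG_INF);  // gap in B (up)
  std::vector<double> Y((size_t)(nA + 1) * W, NEG_INF);  // gap in A (left)
  // predecessor state per cell: 0 = M, 1 = X, 2 = Y
  std::vector<signed char> pM((size_t)(nA + 1) * W, -1), pX = pM, pY = pM;

  M[0] = 0.0;
  for (int i = 1; i <= nA; ++i) {
    X[(size_t)i * W] = -(gap_open + (i - 1) * gap_extend);
    pX[(size_t)i * W] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= nB; ++j) {
    Y[j] = -(gap_open + (j - 1) * gap_extend);
    pY[j] = (j == 1) ? 0 : 2;
  }

  auto best3 = [](double m, double x, double y, signed char &ptr) {
    // tie preference M > X > Y
    if (m >= x && m >= y) { ptr = 0; return m; }
    if (x >= y)           { ptr = 1; return x; }
    ptr = 2; return y;
  };

  for (int i = 1; i <= nA; ++i) {
    const size_t row = (size_t)i * W, prow = (size_t)(i - 1) * W;
    for (int j = 1; j <= nB; ++j) {
      signed char ptr;
      double b = best3(M[prow + j - 1], X[prow + j - 1], Y[prow + j - 1], ptr);
      if (b > NEG_INF) { M[row + j] = b + colscore(i - 1, j - 1); pM[row + j] = ptr; }
      b = best3(M[prow + j] - gap_open, X[prow + j] - gap_extend,
                Y[prow + j] - gap_open, ptr);
      if (b > NEG_INF) { X[row + j] = b; pX[row + j] = ptr; }
      b = best3(M[row + j - 1] - gap_open, X[row + j - 1] - gap_open,
                Y[row + j - 1] - gap_extend, ptr);
      if (b > NEG_INF) { Y[row + j] = b; pY[row + j] = ptr; }
    }
  }

  const size_t end = (size_t)nA * W + nB;
  signed char state;
  double score = best3(M[end], X[end], Y[end], state);

  // traceback: emit column indices (1-based) or NA for a new gap
  std::vector<int> ai, bi;
  int i = nA, j = nB;
  while (i > 0 || j > 0) {
    const size_t c = (size_t)i * W + j;
    signed char prev;
    if (state == 0)      { prev = pM[c]; ai.push_back(i); bi.push_back(j); --i; --j; }
    else if (state == 1) { prev = pX[c]; ai.push_back(i); bi.push_back(NA_INTEGER); --i; }
    else                 { prev = pY[c]; ai.push_back(NA_INTEGER); bi.push_back(j); --j; }
    state = prev;
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());

  return List::create(_["score"] = score,
                      _["a_cols"] = IntegerVector(ai.begin(), ai.end()),
                      _["b_cols"] = IntegerVector(bi.begin(), bi.end()));
}
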