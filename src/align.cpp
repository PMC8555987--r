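#include <Rcpp.h>
using namespace Rcpp;

// Symbol codes used throughout: A=0, C=1, G=2, T=3, N=4, gap=5.
// Scoring: match +1 (identical A/C/G/T), mismatch -1 (N matches nothing,
// including another N), linear gap -2 per gap symbol, gap-vs-gap 0.

struct Scoring {
  double match, mismatch, gap;
  inline double sym(int x, int y) const {
    if (x == 5 && y == 5) return 0.0;
    if (x == 5 || y == 5) return gap;
    if (x == 4 || y == 4) return mismatch;
    return (x == y) ? match : mismatch;
  }
};

// [[Rcpp::export(name = ".align_pair_cpp")]]
List align_pair_cpp(IntegerVector a, IntegerVector b,
                    double match, double mismatch, double gap) {
  Scoring sc{match, mismatch, gap};
  const double GAP = gap;
  int n = a.size(), m = b.size();
  NumericMatrix M(n + 1, m + 1);
  for (int i = 1; i <= n; ++i) M(i, 0) = i * GAP;
  for (int j = 1; j <= m; ++j) M(0, j) = j * GAP;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double diag = M(i - 1, j - 1) + sc.sym(a[i - 1], b[j - 1]);
      double up = M(i - 1, j) + GAP;
      double left = M(i, j - 1) + GAP;
      double best = diag;
      if (up > best) best = up;
      if (left > best) best = left;
      M(i, j) = best;
    }
  }
  // Traceback, tie order diagonal > up > left.
  std::vector<int> ra, rb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        M(i, j) == M(i - 1, j - 1) + sc.sym(a[i - 1], b[j - 1])) {
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]); --i; --j;
    } else if (i > 0 && M(i, j) == M(i - 1, j) + GAP) {
      ra.push_back(a[i - 1]); rb.push_back(5); --i;
    } else {
      ra.push_back(5); rb.push_back(b[j - 1]); --j;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["a"] = wrap(ra), _["b"] = wrap(rb),
                      _["score"] = M(n, m));
}

// Profile-profile global alignment. Profiles are integer matrices
// (rows = sequences, cols = alignment columns, codes 0..5). Column-column
// score is the mean pairwise symbol score over all row pairs; aligning a
// profile column against a gap costs the flat gap penalty.
// [[Rcpp::export(name = ".align_profiles_cpp")]]
List align_profiles_cpp(IntegerMatrix A, IntegerMatrix B,
                        double match, double mismatch, double gap) {
  Scoring sc{match, mismatch, gap};
  const double GAP = gap;
  int nA = A.nrow(), wA = A.ncol(), nB = B.nrow(), wB = B.ncol();
  // per-column symbol counts
  NumericMatrix cA(6, wA), cB(6, wB);
  for (int c = 0; c < wA; ++c)
    for (int r = 0; r < nA; ++r) cA(A(r, c), c) += 1.0;
  for (int c = 0; c < wB; ++c)
    for (int r = 0; r < nB; ++r) cB(B(r, c), c) += 1.0;
  // For each column of B precompute w[x] = sum_y cB[y] * S(x, y)
  NumericMatrix wBx(6, wB);
  for (int c = 0; c < wB; ++c)
    for (int x = 0; x < 6; ++x) {
      double s = 0.0;
      for (int y = 0; y < 6; ++y) s += cB(y, c) * sc.sym(x, y);
      wBx(x, c) = s;
    }
  double denom = (double)nA * (double)nB;
  NumericMatrix M(wA + 1, wB + 1);
  for (int i = 1; i <= wA; ++i) M(i, 0) = i * GAP;
  for (int j = 1; j <= wB; ++j) M(0, j) = j * GAP;
  std::vector<double> colscore((size_t)wA * wB);
  for (int i = 0; i < wA; ++i)
    for (int j = 0; j < wB; ++j) {
      double s = 0.0;
      for (int x = 0; x < 6; ++x)
        if (cA(x, i) > 0) s += cA(x, i) * wBx(x, j);
      colscore[(size_t)i * wB + j] = s / denom;
    }
  for (int i = 1; i <= wA; ++i) {
    for (int j = 1; j <= wB; ++j) {
      double diag = M(i - 1, j - 1) + colscore[(size_t)(i - 1) * wB + (j - 1)];
      double up = M(i - 1, j) + GAP;
      double left = M(i, j - 1) + GAP;
      double best = diag;
      if (up > best) best = up;
      if (left > best) best = left;
      M(i, j) = best;
    }
  }
  std::vector<int> ops; // 0 = both, 1 = A col vs gap, 2 = gap vs B col
  int i = wA, j = wB;
  const double eps = 1e-9;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        std::abs(M(i, j) - (M(i - 1, j - 1) +
                            colscore[(size_t)(i - 1) * wB + (j - 1)])) < eps) {
      ops.push_back(0); --i; --j;
    } else if (i > 0 && std::abs(M(i, j) - (M(i - 1, j) + GAP)) < eps) {
      ops.push_back(1); --i;
    } else {
      ops.push_back(2); --j;
    }
  }
  std::reverse(ops.begin(), ops.end());
  int W = ops.size();
  IntegerMatrix out(nA + nB, W);
  int ci = 0, cj = 0;
  for (int k = 0; k < W; ++k) {
    int op = ops[k];
    if (op == 0 || op == 1) {
      for (int r = 0; r < nA; ++r) out(r, k) = A(r, ci);
      ++ci;
    } else {
      for (int r = 0; r < nA; ++r) out(r, k) = 5;
    }
    if (op == 0 || op == 2) {
      for (int r = 0; r < nB; ++r) out(nA + r, k) = B(r, cj);
      ++cj;
    } else {
      for (int r = 0; r < nB; ++r) out(nA + r, k) = 5;
    }
  }
  return List::create(_["alignment"] = out, _["score"] = M(wA, wB));
}

// Pairwise p-distances over an alignment matrix (codes 0..5). Comparable
// columns are those where both rows are non-gap; N counts as a mismatch.
// [[Rcpp::export(name = ".pdistance_cpp")]]
List pdistance_cpp(IntegerMatrix A) {
  int n = A.nrow(), w = A.ncol();
  NumericMatrix d(n, n);
  IntegerMatrix comp(n, n);
  for (int i = 0; i < n; ++i) {
    comp(i, i) = w;
    for (int j = i + 1; j < n; ++j) {
      int ncomp = 0, nmis = 0;
      for (int c = 0; c < w; ++c) {
        int x = A(i, c), y = A(j, c);
        if (x == 5 || y == 5) continue;
        ++ncomp;
        if (x == 4 || y == 4 || x != y) ++nmis;
      }
      comp(i, j) = comp(j, i) = ncomp;
      d(i, j) = d(j, i) = (ncomp > 0) ? (double)nmis / ncomp : NA_REAL;
    }
  }
  return List::create(_["d"] = d, _["comparable"] = comp);
}
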