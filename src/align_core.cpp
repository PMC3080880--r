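#include <Rcpp.h>
using namespace Rcpp;

// Global (end-to-end) affine-gap alignment of two column sequences given a
// precomputed column-vs-column similarity matrix (Gotoh three-state DP).
//
// Gap run of length L costs open + L * extend (EMBOSS convention), end gaps
// included. Ties are broken deterministically: diagonal (M) over up (gap in
// the second profile, state X) over left (gap in the first profile, state Y),
// both when filling the matrices and at traceback, so exactly one optimal
// alignment is produced.
//
// Returns a list with the optimal score and the traceback path encoded as
// 1 = diagonal, 2 = up (consume a column of profile 1), 3 = left.

static const double NEG_INF = -1e30;

// [[Rcpp::export(name = ".gotoh_align")]]
List gotoh_align(NumericMatrix sim, double gap_open, double gap_extend) {
  const int n1 = sim.nrow(), n2 = sim.ncol();
  const double go = gap_open, ge = gap_extend;
  const double open_cost = go + ge;

  // Scores kept in rolling rows; tracebacks (predecessor state 0=M,1=X,2=Y)
  // kept in full byte matrices of (n1+1) x (n2+1).
  const int R = n1 + 1, C = n2 + 1;
  std::vector<double> pM(C), pX(C), pY(C), cM(C), cX(C), cY(C);
  std::vector<signed char> tM((size_t)R * C, -1), tX((size_t)R * C, -1),
      tY((size_t)R * C, -1);
  const double *simp = REAL(sim);  // column-major n1 x n2

  pM[0] = 0.0;
  pX[0] = pY[0] = NEG_INF;
  for (int j = 1; j < C; ++j) {
    pM[j] = pX[j] = NEG_INF;
    pY[j] = -(go + j * ge);
    tY[j] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i < R; ++i) {
    signed char *tMi = &tM[(size_t)i * C];
    signed char *tXi = &tX[(size_t)i * C];
    signed char *tYi = &tY[(size_t)i * C];
    cM[0] = cY[0] = NEG_INF;
    cX[0] = -(go + i * ge);
    tXi[0] = (i == 1) ? 0 : 1;
    for (int j = 1; j < C; ++j) {
      // M: diagonal move, preference M > X > Y on ties.
      double m = pM[j - 1], x = pX[j - 1], y = pY[j - 1];
      double best = m;
      signed char who = 0;
      if (x > best) { best = x; who = 1; }
      if (y > best) { best = y; who = 2; }
      cM[j] = best + simp[(size_t)(j - 1) * n1 + (i - 1)];
      tMi[j] = who;
      // X: consume row i of profile 1 (gap in profile 2).
      m = pM[j] - open_cost; x = pX[j] - ge; y = pY[j] - open_cost;
      best = m; who = 0;
      if (x > best) { best = x; who = 1; }
      if (y > best) { best = y; who = 2; }
      cX[j] = best;
      tXi[j] = who;
      // Y: consume column j of profile 2 (gap in profile 1).
      m = cM[j - 1] - open_cost; x = cX[j - 1] - open_cost;
      y = cY[j - 1] - ge;
      best = m; who = 0;
      if (x > best) { best = x; who = 1; }
      if (y > best) { best = y; who = 2; }
      cY[j] = best;
      tYi[j] = who;
    }
    std::swap(pM, cM); std::swap(pX, cX); std::swap(pY, cY);
  }

  double best = pM[n2];
  int state = 0;
  if (pX[n2] > best) { best = pX[n2]; state = 1; }
  if (pY[n2] > best) { best = pY[n2]; state = 2; }

  // Traceback.
  std::vector<int> path;
  path.reserve(n1 + n2);
  int i = n1, j = n2;
  while (i > 0 || j > 0) {
    size_t at = (size_t)i * C + j;
    if (state == 0) {
      path.push_back(1);
      state = tM[at];
      --i; --j;
    } else if (state == 1) {
      path.push_back(2);
      state = tX[at];
      --i;
    } else {
      path.push_back(3);
      state = tY[at];
      --j;
    }
  }
  std::reverse(path.begin(), path.end());

  return List::create(_["score"] = best,
                      _["path"] = IntegerVector(path.begin(), path.end()));
}

// Pairwise proportion of differing sites (pairwise deletion) over an
// integer-coded alignment: codes 1..4 = A,C,G,T; NA = gap/ambiguity.
// Returns list with p (proportion differing) and n (comparable sites).

// [[Rcpp::export(name = ".pairwise_pdist")]]
List pairwise_pdist(IntegerMatrix codes) {
  const int n = codes.nrow(), L = codes.ncol();
  NumericMatrix p(n, n), nn(n, n);
  for (int a = 0; a < n; ++a) {
    for (int b = a + 1; b < n; ++b) {
      int nc = 0, nd = 0;
      for (int s = 0; s < L; ++s) {
        int x = codes(a, s), y = codes(b, s);
        if (x != NA_INTEGER && y != NA_INTEGER) {
          ++nc;
          if (x != y) ++nd;
        }
      }
      double pp = (nc > 0) ? (double)nd / nc : NA_REAL;
      p(a, b) = pp; p(b, a) = pp;
      nn(a, b) = nc; nn(b, a) = nc;
    }
  }
  return List::create(_["p"] = p, _["n"] = nn);
}
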