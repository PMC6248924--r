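#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap pairwise DP (Gotoh) over a precomputed cell score matrix.
// Smat[i,j] = substitution score of a[i] vs b[j]. Gap of length k costs
// gap_open + (k-1)*gap_extend. Tie-breaking: diagonal > up (gap in b) > left.
// excl_band > 0 forbids cells with |i-j| < excl_band (self-alignment seeding).

static const double NEG_INF = -1e30;

// [[Rcpp::export]]
List cpp_align_matrix(NumericMatrix Smat, double gap_open, double gap_extend,
                      bool local, int excl_band) {
  const int n = Smat.nrow(), m = Smat.ncol();
  if (n < 1 || m < 1) stop("empty sequence");

  // state matrices: M (diag), X (up: consume a, gap in b), Y (left)
  std::vector<double> Mv((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Xv((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Yv((n + 1) * (m + 1), NEG_INF);
  // pointers: pM: 0 start, 1 from M, 2 from X, 3 from Y
  //           pX/pY: 1 from M, 2 from X, 3 from Y
  std::vector<unsigned char> pM((n + 1) * (m + 1), 0);
  std::vector<unsigned char> pX((n + 1) * (m + 1), 0);
  std::vector<unsigned char> pY((n + 1) * (m + 1), 0);
  const int W = m + 1;
#define IDX(i, j) ((i) * W + (j))

  Mv[IDX(0, 0)] = 0.0;
  if (!local) {
    for (int i = 1; i <= n; ++i) {
      Xv[IDX(i, 0)] = -gap_open - (i - 1) * gap_extend;
      pX[IDX(i, 0)] = (i == 1) ? 1 : 2;
    }
    for (int j = 1; j <= m; ++j) {
      Yv[IDX(0, j)] = -gap_open - (j - 1) * gap_extend;
      pY[IDX(0, j)] = (j == 1) ? 1 : 3;
    }
  }

  double best = local ? 0.0 : NEG_INF;
  int bi = 0, bj = 0;

  // row-major copy of the score matrix for cache-friendly inner loops
  std::vector<double> Srm((size_t)n * m);
  {
    const double* sp = REAL(Smat);
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < m; ++j)
        Srm[(size_t)i * m + j] = sp[(size_t)j * n + i];
  }

  double* Mp = Mv.data(); double* Xp = Xv.data(); double* Yp = Yv.data();
  unsigned char* pMp = pM.data(); unsigned char* pXp = pX.data();
  unsigned char* pYp = pY.data();

  for (int i = 1; i <= n; ++i) {
    const double* srow = &Srm[(size_t)(i - 1) * m];
    double* Mr = Mp + (size_t)i * W; const double* Mu = Mp + (size_t)(i - 1) * W;
    double* Xr = Xp + (size_t)i * W; const double* Xu = Xp + (size_t)(i - 1) * W;
    double* Yr = Yp + (size_t)i * W; const double* Yu = Yp + (size_t)(i - 1) * W;
    unsigned char* pMr = pMp + (size_t)i * W;
    unsigned char* pXr = pXp + (size_t)i * W;
    unsigned char* pYr = pYp + (size_t)i * W;
    for (int j = 1; j <= m; ++j) {
      if (excl_band > 0 && std::abs(i - j) < excl_band) continue;
      // M state
      double prev = Mu[j - 1]; unsigned char pm = 1;
      if (Xu[j - 1] > prev) { prev = Xu[j - 1]; pm = 2; }
      if (Yu[j - 1] > prev) { prev = Yu[j - 1]; pm = 3; }
      if (local && 0.0 > prev) { prev = 0.0; pm = 0; }
      if (prev > NEG_INF / 2) {
        const double mv = prev + srow[j - 1];
        Mr[j] = mv; pMr[j] = pm;
        if (local && mv > best) { best = mv; bi = i; bj = j; }
      }
      // X state (consume a[i-1] against gap)
      double xb = Mu[j] - gap_open; unsigned char px = 1;
      double xx = Xu[j] - gap_extend;
      if (xx > xb) { xb = xx; px = 2; }
      double xy = Yu[j] - gap_open;
      if (xy > xb) { xb = xy; px = 3; }
      if (xb > NEG_INF / 2) { Xr[j] = xb; pXr[j] = px; }
      // Y state (consume b[j-1] against gap)
      double yb = Mr[j - 1] - gap_open; unsigned char py = 1;
      double yx = Xr[j - 1] - gap_open;
      if (yx > yb) { yb = yx; py = 2; }
      double yy = Yr[j - 1] - gap_extend;
      if (yy > yb) { yb = yy; py = 3; }
      if (yb > NEG_INF / 2) { Yr[j] = yb; pYr[j] = py; }
    }
  }

  int ei, ej; unsigned char estate; double score;
  if (local) {
    score = best; ei = bi; ej = bj; estate = 1; // M
    if (best <= 0.0) {
      return List::create(_["score"] = 0.0, _["a_start"] = 0, _["a_end"] = -1,
                          _["b_start"] = 0, _["b_end"] = -1,
                          _["a_idx"] = IntegerVector(0),
                          _["b_idx"] = IntegerVector(0));
    }
  } else {
    double eM = Mv[IDX(n, m)], eX = Xv[IDX(n, m)], eY = Yv[IDX(n, m)];
    score = eM; estate = 1;
    if (eX > score) { score = eX; estate = 2; }
    if (eY > score) { score = eY; estate = 3; }
    ei = n; ej = m;
    if (score < NEG_INF / 2) stop("no admissible alignment path");
  }

  // traceback
  std::vector<int> ai, bi2;
  int i = ei, j = ej; unsigned char st = estate;
  while (i > 0 || j > 0) {
    const int id = IDX(i, j);
    if (st == 1) { // M
      unsigned char p = pM[id];
      ai.push_back(i - 1); bi2.push_back(j - 1);
      --i; --j;
      if (local && p == 0) break;
      st = (p == 0) ? 1 : p;
    } else if (st == 2) { // X: a vs gap
      unsigned char p = pX[id];
      ai.push_back(i - 1); bi2.push_back(-1);
      --i;
      st = p;
    } else { // Y
      unsigned char p = pY[id];
      ai.push_back(-1); bi2.push_back(j - 1);
      --j;
      st = p;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi2.begin(), bi2.end());

  int as = -1, ae = -1, bs = -1, be = -1;
  for (size_t k = 0; k < ai.size(); ++k) {
    if (ai[k] >= 0) { if (as < 0) as = ai[k]; ae = ai[k]; }
    if (bi2[k] >= 0) { if (bs < 0) bs = bi2[k]; be = bi2[k]; }
  }
  return List::create(_["score"] = score, _["a_start"] = as, _["a_end"] = ae,
                      _["b_start"] = bs, _["b_end"] = be,
                      _["a_idx"] = wrap(ai), _["b_idx"] = wrap(bi2));
#undef IDX
}

// Windowed dot-plot: D[i,j] = sum of P[i+k, j+k] over k in [-h, h],
// truncated at matrix edges.
// [[Rcpp::export]]
NumericMatrix cpp_dotplot(NumericMatrix P, int window) {
  const int n = P.nrow(), m = P.ncol();
  const int h = window / 2;
  NumericMatrix D(n, m);
  for (int d = -(n - 1); d <= m - 1; ++d) {
    // diagonal cells (i, i + d)
    int i0 = std::max(0, -d), i1 = std::min(n - 1, m - 1 - d);
    int len = i1 - i0 + 1;
    if (len <= 0) continue;
    std::vector<double> v(len), cs(len + 1, 0.0);
    for (int t = 0; t < len; ++t) v[t] = P(i0 + t, i0 + t + d);
    for (int t = 0; t < len; ++t) cs[t + 1] = cs[t] + v[t];
    for (int t = 0; t < len; ++t) {
      int lo = std::max(0, t - h), hi = std::min(len - 1, t + h);
      D(i0 + t, i0 + t + d) = cs[hi + 1] - cs[lo];
    }
  }
  return D;
}
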