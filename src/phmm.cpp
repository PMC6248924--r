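#include <Rcpp.h>
using namespace Rcpp;

// Uni-hit local profile-HMM scoring in log-odds space.
//
// Model: S -> N (background flank, self-loop prob r) -> B -> M_k (uniform
// entry) -> core {M,I,D} -> E -> C (background flank, self-loop prob r) -> T.
// Insert and flank emissions equal the null background, so they contribute
// zero log-odds; match emissions enter as log2-odds converted to nats here.
// The null model emits each residue from the background with continue prob r,
// so the reported bit score is (C[n] - n*ln r) / ln 2.

static const double NEG = -1e30;

// [[Rcpp::export]]
double cpp_phmm_forward(IntegerVector xi, NumericMatrix lodds,
                        NumericVector lnBM, double lnNB,
                        NumericVector lME,
                        NumericVector lMM, NumericVector lMI, NumericVector lMD,
                        NumericVector lIM, NumericVector lII,
                        NumericVector lDM, NumericVector lDD,
                        double ln_r) {
  const int n = xi.size(), L = lodds.nrow();
  if (n < 1) stop("empty sequence");
  // scaled linear-space recursion: all state values are odds relative to
  // a running scale exp(logS), renormalised per row, so the inner loop is
  // pure multiply/add (exact up to double rounding)
  const double r = std::exp(ln_r);
  const double entry0 = std::exp(lnNB); // N -> B
  std::vector<double> EO((size_t)L * 21), eBM(L), eME(L);
  {
    const double* lo = REAL(lodds);
    for (size_t k = 0; k < (size_t)L * 21; ++k) EO[k] = std::exp(lo[k]);
    for (int j = 0; j < L; ++j) {
      eBM[j] = std::exp(lnBM[j]);
      eME[j] = std::exp(lME[j]);
    }
  }
  std::vector<double> eMM(std::max(L - 1, 0)), eMI(std::max(L - 1, 0)),
      eMD(std::max(L - 1, 0)), eIM(std::max(L - 1, 0)),
      eII(std::max(L - 1, 0)), eDM(std::max(L - 1, 0)),
      eDD(std::max(L - 1, 0));
  for (int j = 0; j < L - 1; ++j) {
    eMM[j] = std::exp(lMM[j]); eMI[j] = std::exp(lMI[j]);
    eMD[j] = std::exp(lMD[j]); eIM[j] = std::exp(lIM[j]);
    eII[j] = std::exp(lII[j]); eDM[j] = std::exp(lDM[j]);
    eDD[j] = std::exp(lDD[j]);
  }
  std::vector<double> vm(L, 0.0), vi(L, 0.0), vd(L, 0.0);
  std::vector<double> nm(L), ni(L), nd(L);
  double C = 0.0, Nrel = 1.0, logS = 0.0;
  const int* px = INTEGER(xi);

  for (int i = 1; i <= n; ++i) {
    const int x = px[i - 1];
    const double* eo = EO.data() + (size_t)x * L;
    const double* pvm = vm.data(); const double* pvi = vi.data();
    const double* pvd = vd.data();
    double* pnm = nm.data(); double* pni = ni.data(); double* pnd = nd.data();
    const double ent = Nrel * entry0;
    pnm[0] = eo[0] * ent * eBM[0];
    if (L > 1) pni[0] = pvm[0] * eMI[0] + pvi[0] * eII[0];
    for (int j = 1; j < L; ++j) {
      pnm[j] = eo[j] * (ent * eBM[j] + pvm[j - 1] * eMM[j - 1] +
                        pvi[j - 1] * eIM[j - 1] + pvd[j - 1] * eDM[j - 1]);
      if (j < L - 1) pni[j] = pvm[j] * eMI[j] + pvi[j] * eII[j];
    }
    if (L > 1) pni[L - 1] = 0.0;
    pnd[0] = 0.0;
    for (int j = 1; j < L; ++j)
      pnd[j] = pnm[j - 1] * eMD[j - 1] + pnd[j - 1] * eDD[j - 1];
    double E = pnd[L - 1]; // D_L -> E with prob 1
    for (int j = 0; j < L; ++j) E += pnm[j] * eME[j];
    C = E + C * r;
    Nrel *= r;
    // rescale by the row maximum
    double s = C > Nrel ? C : Nrel;
    for (int j = 0; j < L; ++j) {
      if (pnm[j] > s) s = pnm[j];
      if (pni[j] > s) s = pni[j];
      if (pnd[j] > s) s = pnd[j];
    }
    if (s > 0 && (s > 1e100 || s < 1e-100)) {
      const double inv = 1.0 / s;
      for (int j = 0; j < L; ++j) { pnm[j] *= inv; pni[j] *= inv; pnd[j] *= inv; }
      C *= inv; Nrel *= inv;
      logS += std::log(s);
    }
    vm.swap(nm); vi.swap(ni); vd.swap(nd);
  }
  if (C <= 0) return R_NegInf;
  return (std::log(C) + logS - n * ln_r) / std::log(2.0);
}

// Viterbi with traceback. Tie-breaking among predecessors: M > D > I > entry.
// Returns the bit score of the best path, the 1-based residue interval
// emitted by core (M/I) states, the match-node interval, and the full path.
// [[Rcpp::export]]
List cpp_phmm_viterbi(IntegerVector xi, NumericMatrix lodds,
                      NumericVector lnBM, double lnNB,
                      NumericVector lME,
                      NumericVector lMM, NumericVector lMI, NumericVector lMD,
                      NumericVector lIM, NumericVector lII,
                      NumericVector lDM, NumericVector lDD,
                      double ln_r) {
  const int n = xi.size(), L = lodds.nrow();
  if (n < 1) stop("empty sequence");
  std::vector<double> vm(L, NEG), vi(L, NEG), vd(L, NEG);
  std::vector<double> nm(L), ni(L), nd(L);
  // pointers per (i, j); i is 1-based row index into these arrays
  std::vector<unsigned char> pm((n + 1) * L, 0), pi_((n + 1) * L, 0),
      pd((n + 1) * L, 0);
  std::vector<int> eBestJ(n + 1, -1);
  std::vector<unsigned char> eFromD(n + 1, 0), cFromE(n + 1, 0);
  std::vector<double> Ev(n + 1, NEG);
  double C = NEG;

  for (int i = 1; i <= n; ++i) {
    const int x = xi[i - 1];
    const double lnN = (i - 1) * ln_r;
    for (int j = 0; j < L; ++j) {
      double best; unsigned char p;
      if (j > 0) {
        best = vm[j - 1] + lMM[j - 1]; p = 1;
        double cd = vd[j - 1] + lDM[j - 1];
        if (cd > best) { best = cd; p = 3; }
        double ci = vi[j - 1] + lIM[j - 1];
        if (ci > best) { best = ci; p = 2; }
        double ce = lnN + lnNB + lnBM[j];
        if (ce > best) { best = ce; p = 0; }
      } else {
        best = lnN + lnNB + lnBM[0]; p = 0;
      }
      nm[j] = lodds(j, x) + best;
      pm[i * L + j] = p;
      if (j < L - 1) {
        double bm = vm[j] + lMI[j], bi = vi[j] + lII[j];
        if (bm >= bi) { ni[j] = bm; pi_[i * L + j] = 1; }
        else { ni[j] = bi; pi_[i * L + j] = 2; }
      } else ni[j] = NEG;
    }
    nd[0] = NEG;
    for (int j = 1; j < L; ++j) {
      double bm = nm[j - 1] + lMD[j - 1], bd = nd[j - 1] + lDD[j - 1];
      if (bm >= bd) { nd[j] = bm; pd[i * L + j] = 1; }
      else { nd[j] = bd; pd[i * L + j] = 3; }
    }
    double E = NEG; int bj = -1; unsigned char fd = 0;
    for (int j = 0; j < L; ++j) {
      double c = nm[j] + lME[j];
      if (c > E) { E = c; bj = j; fd = 0; }
    }
    if (nd[L - 1] > E) { E = nd[L - 1]; bj = L - 1; fd = 1; }
    Ev[i] = E; eBestJ[i] = bj; eFromD[i] = fd;
    double cl = C + ln_r;
    if (E >= cl) { C = E; cFromE[i] = 1; } else { C = cl; cFromE[i] = 0; }
    vm.swap(nm); vi.swap(ni); vd.swap(nd);
  }
  if (C < NEG / 2)
    return List::create(_["bits"] = R_NegInf, _["start"] = NA_INTEGER,
                        _["end"] = NA_INTEGER);
  const double bits = (C - n * ln_r) / std::log(2.0);

  int cur = n;
  while (cur > 0 && !cFromE[cur]) --cur;
  const int i_end = cur;
  int i = i_end, j = eBestJ[i_end];
  int state = eFromD[i_end] ? 3 : 1; // 1=M, 2=I, 3=D
  std::vector<int> p_state, p_node, p_pos;
  int i_start = i_end, k_start = j, k_end = j;
  bool done = false;
  while (!done) {
    p_state.push_back(state); p_node.push_back(j + 1);
    p_pos.push_back(state == 3 ? 0 : i);
    if (state != 3) i_start = i;
    if (j < k_start) k_start = j;
    if (j > k_end) k_end = j;
    if (state == 1) {
      unsigned char p = pm[i * L + j];
      if (p == 0) { done = true; }
      else if (p == 1) { --i; --j; state = 1; }
      else if (p == 2) { --i; --j; state = 2; }
      else { --i; --j; state = 3; }
    } else if (state == 2) {
      unsigned char p = pi_[i * L + j];
      state = (p == 1) ? 1 : 2;
      --i;
    } else {
      unsigned char p = pd[i * L + j];
      state = (p == 1) ? 1 : 3;
      --j;
    }
  }
  std::reverse(p_state.begin(), p_state.end());
  std::reverse(p_node.begin(), p_node.end());
  std::reverse(p_pos.begin(), p_pos.end());
  return List::create(_["bits"] = bits, _["start"] = i_start,
                      _["end"] = i_end, _["node_start"] = k_start + 1,
                      _["node_end"] = k_end + 1,
                      _["path_state"] = wrap(p_state),
                      _["path_node"] = wrap(p_node),
                      _["path_pos"] = wrap(p_pos));
}
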