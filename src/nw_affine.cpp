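#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap Needleman-Wunsch (Gotoh) on a precomputed similarity matrix,
// with free end gaps (semi-global) as appropriate for threading structure
// fragments of unequal length. Ties are broken toward the diagonal so that
// ungapped correspondences are preferred. Returns the matched index pairs
// (1-based, strictly increasing in both sequences).
//
// S: n x m similarity matrix (larger = more similar; here 1/(1+(d/d0)^2)).
// gap_open: score added when opening a gap (negative).
// gap_extend: score added per additional gap position (<= 0).

// [[Rcpp::export(name = ".nw_affine")]]
IntegerMatrix nw_affine(NumericMatrix S, double gap_open, double gap_extend) {
  const int n = S.nrow(), m = S.ncol();
  const double NEG = -1e30;
  // state 0 = M (i,j aligned), 1 = E (gap in rows: j consumed unpaired),
  // 2 = F (gap in cols: i consumed unpaired)
  std::vector<double> M((n + 1) * (m + 1), NEG), E(M), F(M);
  std::vector<unsigned char> pM((n + 1) * (m + 1), 0), pE(pM), pF(pM);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  // free leading gaps: any prefix of either sequence may be skipped
  for (int j = 0; j <= m; ++j) { M[at(0, j)] = 0.0; E[at(0, j)] = NEG; }
  for (int i = 0; i <= n; ++i) { M[at(i, 0)] = 0.0; F[at(i, 0)] = NEG; }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // M: diagonal preferred on ties (order M >= E >= F)
      double dM = M[at(i - 1, j - 1)], dE = E[at(i - 1, j - 1)],
             dF = F[at(i - 1, j - 1)];
      unsigned char pm = 0; double best = dM;
      if (dE > best) { best = dE; pm = 1; }
      if (dF > best) { best = dF; pm = 2; }
      M[at(i, j)] = S(i - 1, j - 1) + best;
      pM[at(i, j)] = pm;
      // E: gap consuming column j
      double eo = M[at(i, j - 1)] + gap_open;
      double ee = E[at(i, j - 1)] + gap_extend;
      if (eo >= ee) { E[at(i, j)] = eo; pE[at(i, j)] = 0; }
      else          { E[at(i, j)] = ee; pE[at(i, j)] = 1; }
      // F: gap consuming row i
      double fo = M[at(i - 1, j)] + gap_open;
      double fe = F[at(i - 1, j)] + gap_extend;
      if (fo >= fe) { F[at(i, j)] = fo; pF[at(i, j)] = 0; }
      else          { F[at(i, j)] = fe; pF[at(i, j)] = 1; }
    }
  }

  // free trailing gaps: best M on the last row or column
  int bi = n, bj = m;
  double best = M[at(n, m)];
  for (int j = m; j >= 1; --j)
    if (M[at(n, j)] > best) { best = M[at(n, j)]; bi = n; bj = j; }
  for (int i = n; i >= 1; --i)
    if (M[at(i, m)] > best) { best = M[at(i, m)]; bi = i; bj = m; }

  std::vector<int> ia, ja;
  int i = bi, j = bj, state = 0;
  while (i > 0 && j > 0) {
    if (state == 0) {
      ia.push_back(i); ja.push_back(j);
      unsigned char pm = pM[at(i, j)];
      --i; --j;
      if (i == 0 || j == 0) break;
      // a boundary M of value 0 with no incoming pair means "start here"
      state = pm;
    } else if (state == 1) {
      state = pE[at(i, j)] == 0 ? 0 : 1;
      --j;
    } else {
      state = pF[at(i, j)] == 0 ? 0 : 2;
      --i;
    }
  }
  const int k = (int)ia.size();
  IntegerMatrix out(k, 2);
  for (int q = 0; q < k; ++q) {  // reverse into increasing order
    out(q, 0) = ia[k - 1 - q];
    out(q, 1) = ja[k - 1 - q];
  }
  return out;
}
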