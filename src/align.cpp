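#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Affine-gap pairwise alignment kernels shared by the homology, clustering,
// ctld and phylo layers.  Sequences arrive as 0-based integer codes into the
// rows/columns of the scoring matrix S.  A gap of length L costs
// gap_open + L * gap_ext (both magnitudes, >= 0).

static const double NEG_INF = -1e30;

struct Cell { double s; int m; };     // score, matches (lexicographic value)

static inline bool lexGreater(double s1, int m1, double s2, int m2) {
  if (s1 > s2 + 1e-9) return true;
  if (s1 < s2 - 1e-9) return false;
  return m1 > m2;
}

// ---------------------------------------------------------------- local SW
// Smith-Waterman-Gotoh.  Returns best score, 1-based inclusive endpoints in
// a and b (0s when the optimal local alignment is empty), match count,
// alignment length and the aligned index vectors (0 = gap).
// [[Rcpp::export(name = ".sw_align")]]
List sw_align(IntegerVector a, IntegerVector b, NumericMatrix S,
              double gap_open, double gap_ext) {
  const int n = a.size(), m = b.size();
  // M is only defined where an alignment can end in a substitution column;
  // boundary cells stay -inf so tracebacks never walk off the grid, and
  // local alignments start through the explicit 0 option (pointer 0).
  std::vector<double> M((n + 1) * (m + 1), NEG_INF),
                      X((n + 1) * (m + 1), NEG_INF),
                      Y((n + 1) * (m + 1), NEG_INF);
  M[0] = 0.0;
  // traceback pointers: for M: 0=start,1=diag from M,2=diag from X,3=diag from Y
  // for X: 1=from M above, 2=from X above; for Y: 1=from M left, 2=from Y left
  std::vector<signed char> pM((n + 1) * (m + 1), 0),
                           pX((n + 1) * (m + 1), 0),
                           pY((n + 1) * (m + 1), 0);
  double best = 0.0; int bi = 0, bj = 0;
  const double go = gap_open, ge = gap_ext;
  for (int i = 1; i <= n; ++i) {
    const int ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      const int idx = i * (m + 1) + j;
      const int up = (i - 1) * (m + 1) + j;
      const int lf = i * (m + 1) + j - 1;
      const int dg = (i - 1) * (m + 1) + j - 1;
      // X: gap in b (consume a)
      double x1 = M[up] - go - ge, x2 = X[up] - ge;
      if (x1 >= x2) { X[idx] = x1; pX[idx] = 1; } else { X[idx] = x2; pX[idx] = 2; }
      // Y: gap in a (consume b)
      double y1 = M[lf] - go - ge, y2 = Y[lf] - ge;
      if (y1 >= y2) { Y[idx] = y1; pY[idx] = 1; } else { Y[idx] = y2; pY[idx] = 2; }
      // M
      double sc = S(ai, b[j - 1]);
      double c0 = 0.0, c1 = M[dg], c2 = X[dg], c3 = Y[dg];
      double cb = c1; signed char pb = 1;
      if (c2 > cb) { cb = c2; pb = 2; }
      if (c3 > cb) { cb = c3; pb = 3; }
      if (c0 > cb) { cb = c0; pb = 0; }
      M[idx] = cb + sc;
      pM[idx] = pb;
      if (M[idx] < 0) { M[idx] = NEG_INF; pM[idx] = 0; } // clamp: local restart
      if (M[idx] > best) { best = M[idx]; bi = i; bj = j; }
    }
  }
  std::vector<int> av, bv;
  int nmatch = 0;
  if (best > 0) {
    int i = bi, j = bj, layer = 0; // 0=M,1=X,2=Y
    while (i > 0 || j > 0) {
      int idx = i * (m + 1) + j;
      if (layer == 0) {
        av.push_back(i); bv.push_back(j);
        if (a[i - 1] == b[j - 1]) ++nmatch;
        signed char p = pM[idx];
        --i; --j;
        if (p == 0) break;
        layer = (p == 1) ? 0 : (p == 2 ? 1 : 2);
      } else if (layer == 1) {
        av.push_back(i); bv.push_back(0);
        signed char p = pX[idx];
        --i;
        layer = (p == 1) ? 0 : 1;
      } else {
        av.push_back(0); bv.push_back(j);
        signed char p = pY[idx];
        --j;
        layer = (p == 1) ? 0 : 2;
      }
    }
    std::reverse(av.begin(), av.end());
    std::reverse(bv.begin(), bv.end());
  }
  int qs = 0, qe = 0, ss = 0, se = 0;
  for (size_t k = 0; k < av.size(); ++k) {
    if (av[k] > 0) { if (qs == 0) qs = av[k]; qe = av[k]; }
    if (bv[k] > 0) { if (ss == 0) ss = bv[k]; se = bv[k]; }
  }
  return List::create(_["score"] = best > 0 ? best : 0.0,
                      _["q_start"] = qs, _["q_end"] = qe,
                      _["s_start"] = ss, _["s_end"] = se,
                      _["nmatch"] = nmatch,
                      _["aln_length"] = (int)av.size(),
                      _["a_idx"] = wrap(av), _["b_idx"] = wrap(bv));
}

// Score-only Smith-Waterman (linear memory, no traceback): the cheap first
// pass of the similarity search; full alignments are computed only for
// pairs that reach the score threshold.
// [[Rcpp::export(name = ".sw_score")]]
double sw_score(IntegerVector a, IntegerVector b, NumericMatrix S,
                double gap_open, double gap_ext) {
  const int n = a.size(), m = b.size(), K = S.nrow();
  std::vector<double> Sf(K * K);
  for (int x = 0; x < K; ++x)
    for (int y = 0; y < K; ++y) Sf[x * K + y] = S(x, y);
  std::vector<double> H(m + 1, 0.0), Y(m + 1, NEG_INF);
  const double go = gap_open, ge = gap_ext;
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    const double* Srow = &Sf[a[i - 1] * K];
    double diag = 0.0;       // H[i-1][j-1]
    double x = NEG_INF;      // X state along the row? no: X is per column
    double hprev = 0.0;      // H[i][j-1]
    double yprev = NEG_INF;  // Y[i][j-1]
    for (int j = 1; j <= m; ++j) {
      double xj = std::max(H[j] - go - ge, Y[j] - ge);   // gap consuming a
      double yj = std::max(hprev - go - ge, yprev - ge); // gap consuming b
      double h = diag + Srow[b[j - 1]];
      if (xj > h) h = xj;
      if (yj > h) h = yj;
      if (h < 0) h = 0;
      diag = H[j];
      H[j] = h; Y[j] = xj;
      hprev = h; yprev = yj;
      if (h > best) best = h;
    }
    (void)x;
  }
  return best;
}

// ---------------------------------------------------------------- global NW
// Needleman-Wunsch-Gotoh maximizing (score, matches) lexicographically so the
// reported match count is a well-defined function of the inputs (no
// traceback-tie ambiguity).  End gaps are penalized.
// [[Rcpp::export(name = ".nw_align")]]
List nw_align(IntegerVector a, IntegerVector b, NumericMatrix S,
              double gap_open, double gap_ext) {
  const int n = a.size(), m = b.size();
  const int W = m + 1;
  std::vector<Cell> M((n + 1) * W), X((n + 1) * W), Y((n + 1) * W);
  std::vector<signed char> pM((n + 1) * W, 0), pX((n + 1) * W, 0), pY((n + 1) * W, 0);
  const double go = gap_open, ge = gap_ext;
  for (int i = 0; i <= n; ++i)
    for (int j = 0; j <= m; ++j) {
      M[i * W + j] = {NEG_INF, 0};
      X[i * W + j] = {NEG_INF, 0};
      Y[i * W + j] = {NEG_INF, 0};
    }
  M[0] = {0.0, 0};
  for (int i = 1; i <= n; ++i) { X[i * W] = {-go - ge * i, 0}; pX[i * W] = (i == 1) ? 1 : 2; }
  for (int j = 1; j <= m; ++j) { Y[j] = {-go - ge * j, 0}; pY[j] = (j == 1) ? 1 : 2; }
  for (int i = 1; i <= n; ++i) {
    const int ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      const int idx = i * W + j, up = (i - 1) * W + j, lf = i * W + j - 1,
                dg = (i - 1) * W + j - 1;
      // X from above
      {
        double s1 = M[up].s - go - ge; int m1 = M[up].m;
        double s2 = X[up].s - ge;      int m2 = X[up].m;
        if (M[up].s <= NEG_INF / 2) s1 = NEG_INF;
        if (X[up].s <= NEG_INF / 2) s2 = NEG_INF;
        if (lexGreater(s2, m2, s1, m1)) { X[idx] = {s2, m2}; pX[idx] = 2; }
        else                            { X[idx] = {s1, m1}; pX[idx] = 1; }
      }
      // Y from left
      {
        double s1 = M[lf].s - go - ge; int m1 = M[lf].m;
        double s2 = Y[lf].s - ge;      int m2 = Y[lf].m;
        if (M[lf].s <= NEG_INF / 2) s1 = NEG_INF;
        if (Y[lf].s <= NEG_INF / 2) s2 = NEG_INF;
        if (lexGreater(s2, m2, s1, m1)) { Y[idx] = {s2, m2}; pY[idx] = 2; }
        else                            { Y[idx] = {s1, m1}; pY[idx] = 1; }
      }
      // M diagonal
      {
        const int match = (ai == b[j - 1]) ? 1 : 0;
        double sc = S(ai, b[j - 1]);
        Cell best = M[dg]; signed char p = 1;
        if (lexGreater(X[dg].s, X[dg].m, best.s, best.m)) { best = X[dg]; p = 2; }
        if (lexGreater(Y[dg].s, Y[dg].m, best.s, best.m)) { best = Y[dg]; p = 3; }
        if (best.s <= NEG_INF / 2) { M[idx] = {NEG_INF, 0}; pM[idx] = 0; }
        else { M[idx] = {best.s + sc, best.m + match}; pM[idx] = p; }
      }
    }
  }
  const int idxE = n * W + m;
  Cell fin = M[idxE]; int layer = 0;
  if (lexGreater(X[idxE].s, X[idxE].m, fin.s, fin.m)) { fin = X[idxE]; layer = 1; }
  if (lexGreater(Y[idxE].s, Y[idxE].m, fin.s, fin.m)) { fin = Y[idxE]; layer = 2; }
  // traceback
  std::vector<int> av, bv;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int idx = i * W + j;
    if (layer == 0) {
      av.push_back(i); bv.push_back(j);
      signed char p = pM[idx];
      --i; --j;
      layer = (p == 1) ? 0 : (p == 2 ? 1 : 2);
    } else if (layer == 1) {
      av.push_back(i); bv.push_back(0);
      signed char p = pX[idx];
      --i;
      layer = (p == 1) ? 0 : 1;
    } else {
      av.push_back(0); bv.push_back(j);
      signed char p = pY[idx];
      --j;
      layer = (p == 1) ? 0 : 2;
    }
  }
  std::reverse(av.begin(), av.end());
  std::reverse(bv.begin(), bv.end());
  return List::create(_["score"] = fin.s, _["nmatch"] = fin.m,
                      _["aln_length"] = (int)av.size(),
                      _["a_idx"] = wrap(av), _["b_idx"] = wrap(bv));
}

// Score + match count only (no traceback storage): used by the clustering and
// dedupe inner loops where only the identity value is needed.
// [[Rcpp::export(name = ".nw_stats")]]
NumericVector nw_stats(IntegerVector a, IntegerVector b, NumericMatrix S,
                       double gap_open, double gap_ext) {
  const int n = a.size(), m = b.size();
  const int W = m + 1;
  std::vector<Cell> Mp(W), Xp(W), Yp(W), Mc(W), Xc(W), Yc(W);
  const double go = gap_open, ge = gap_ext;
  Mp[0] = {0.0, 0}; Xp[0] = {NEG_INF, 0}; Yp[0] = {NEG_INF, 0};
  for (int j = 1; j <= m; ++j) {
    Mp[j] = {NEG_INF, 0}; Xp[j] = {NEG_INF, 0}; Yp[j] = {-go - ge * j, 0};
  }
  for (int i = 1; i <= n; ++i) {
    const int ai = a[i - 1];
    Mc[0] = {NEG_INF, 0}; Xc[0] = {-go - ge * i, 0}; Yc[0] = {NEG_INF, 0};
    for (int j = 1; j <= m; ++j) {
      // X from row above (same column)
      {
        double s1 = (Mp[j].s <= NEG_INF / 2) ? NEG_INF : Mp[j].s - go - ge;
        double s2 = (Xp[j].s <= NEG_INF / 2) ? NEG_INF : Xp[j].s - ge;
        if (lexGreater(s2, Xp[j].m, s1, Mp[j].m)) Xc[j] = {s2, Xp[j].m};
        else Xc[j] = {s1, Mp[j].m};
      }
      // Y from left (current row)
      {
        double s1 = (Mc[j - 1].s <= NEG_INF / 2) ? NEG_INF : Mc[j - 1].s - go - ge;
        double s2 = (Yc[j - 1].s <= NEG_INF / 2) ? NEG_INF : Yc[j - 1].s - ge;
        if (lexGreater(s2, Yc[j - 1].m, s1, Mc[j - 1].m)) Yc[j] = {s2, Yc[j - 1].m};
        else Yc[j] = {s1, Mc[j - 1].m};
      }
      // M diagonal
      {
        const int match = (ai == b[j - 1]) ? 1 : 0;
        Cell best = Mp[j - 1];
        if (lexGreater(Xp[j - 1].s, Xp[j - 1].m, best.s, best.m)) best = Xp[j - 1];
        if (lexGreater(Yp[j - 1].s, Yp[j - 1].m, best.s, best.m)) best = Yp[j - 1];
        if (best.s <= NEG_INF / 2) Mc[j] = {NEG_INF, 0};
        else Mc[j] = {best.s + S(ai, b[j - 1]), best.m + match};
      }
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }
  Cell fin = Mp[m];
  if (lexGreater(Xp[m].s, Xp[m].m, fin.s, fin.m)) fin = Xp[m];
  if (lexGreater(Yp[m].s, Yp[m].m, fin.s, fin.m)) fin = Yp[m];
  return NumericVector::create(_["score"] = fin.s, _["nmatch"] = (double)fin.m);
}

// -------------------------------------------------------- profile alignment
// Profile-profile global DP for progressive alignment.  fa, fb: residue
// frequency matrices (alphabet x columns, gap excluded, columns may sum to
// < 1 when gapped).  SA = S %*% fa precomputed by the caller is avoided;
// we take the raw pieces to keep the R side simple.
// Returns the merge path as two logical vectors: advance-in-A, advance-in-B.
// [[Rcpp::export(name = ".profile_align")]]
List profile_align(NumericMatrix fa, NumericMatrix fb, NumericMatrix S,
                   double gap_open, double gap_ext) {
  const int n = fa.ncol(), m = fb.ncol(), K = S.nrow();
  // column-pair scores: sc(i,j) = fa_i' S fb_j
  NumericMatrix SB(K, m);
  for (int j = 0; j < m; ++j)
    for (int x = 0; x < K; ++x) {
      double v = 0;
      for (int y = 0; y < K; ++y) v += S(x, y) * fb(y, j);
      SB(x, j) = v;
    }
  const int W = m + 1;
  std::vector<double> M((n + 1) * W, NEG_INF), X((n + 1) * W, NEG_INF),
                      Y((n + 1) * W, NEG_INF);
  std::vector<signed char> pM((n + 1) * W, 0), pX((n + 1) * W, 0), pY((n + 1) * W, 0);
  const double go = gap_open, ge = gap_ext;
  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) { X[i * W] = -go - ge * i; pX[i * W] = (i == 1) ? 1 : 2; }
  for (int j = 1; j <= m; ++j) { Y[j] = -go - ge * j; pY[j] = (j == 1) ? 1 : 2; }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int idx = i * W + j, up = (i - 1) * W + j, lf = i * W + j - 1,
                dg = (i - 1) * W + j - 1;
      double x1 = M[up] - go - ge, x2 = X[up] - ge;
      if (x2 > x1) { X[idx] = x2; pX[idx] = 2; } else { X[idx] = x1; pX[idx] = 1; }
      double y1 = M[lf] - go - ge, y2 = Y[lf] - ge;
      if (y2 > y1) { Y[idx] = y2; pY[idx] = 2; } else { Y[idx] = y1; pY[idx] = 1; }
      double sc = 0;
      for (int x = 0; x < K; ++x) if (fa(x, i - 1) > 0) sc += fa(x, i - 1) * SB(x, j - 1);
      double cb = M[dg]; signed char pb = 1;
      if (X[dg] > cb) { cb = X[dg]; pb = 2; }
      if (Y[dg] > cb) { cb = Y[dg]; pb = 3; }
      M[idx] = cb + sc; pM[idx] = pb;
    }
  }
  const int idxE = n * W + m;
  int layer = 0; double fin = M[idxE];
  if (X[idxE] > fin) { fin = X[idxE]; layer = 1; }
  if (Y[idxE] > fin) { fin = Y[idxE]; layer = 2; }
  std::vector<int> stepA, stepB;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int idx = i * W + j;
    if (layer == 0) {
      stepA.push_back(1); stepB.push_back(1);
      signed char p = pM[idx]; --i; --j;
      layer = (p == 1) ? 0 : (p == 2 ? 1 : 2);
    } else if (layer == 1) {
      stepA.push_back(1); stepB.push_back(0);
      signed char p = pX[idx]; --i;
      layer = (p == 1) ? 0 : 1;
    } else {
      stepA.push_back(0); stepB.push_back(1);
      signed char p = pY[idx]; --j;
      layer = (p == 1) ? 0 : 2;
    }
  }
  std::reverse(stepA.begin(), stepA.end());
  std::reverse(stepB.begin(), stepB.end());
  return List::create(_["score"] = fin, _["step_a"] = wrap(stepA),
                      _["step_b"] = wrap(stepB));
}
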