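#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap local alignment engines.  Residues are integer-encoded
// (1..A over the 20-letter amino-acid alphabet); code 0 means "unknown"
// (X) and scores 0 against everything.  Penalties are positive numbers
// subtracted from the running score.  Tie-break order in both the
// recurrence and the traceback is diagonal (match) > up > left, which
// makes the traceback deterministic.

static const double NEG_INF = -1e30;

// Local alignment of an integer-encoded query against a position-specific
// score matrix S (n_columns x alphabet).  Returns the optimal score and,
// for the optimal traceback, the map from profile column to query position
// (match states only; both 1-based).
// [[Rcpp::export(name = ".profile_sw_cpp")]]
List profile_sw_cpp(NumericMatrix S, IntegerVector q,
                    double gap_open, double gap_extend) {
  const int n = S.nrow();       // profile columns
  const int m = q.size();       // query residues
  const int A = S.ncol();

  // DP over (column i, residue j), 1-based with a zero border.
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  IntegerMatrix tbM(n + 1, m + 1);  // 0 = restart, 1 = from M, 2 = from X, 3 = from Y
  for (int j = 0; j <= m; ++j) { X(0, j) = NEG_INF; Y(0, j) = NEG_INF; }
  for (int i = 0; i <= n; ++i) { X(i, 0) = NEG_INF; Y(i, 0) = NEG_INF; }

  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int code = q[j - 1];
      double sub = 0.0;
      if (code >= 1 && code <= A) sub = S(i - 1, code - 1);

      double dM = M(i - 1, j - 1), dX = X(i - 1, j - 1), dY = Y(i - 1, j - 1);
      double pre = 0.0; int tb = 0;
      if (dM >= dX && dM >= dY && dM >= 0.0) { pre = dM; tb = 1; }
      else if (dX >= dY && dX >= 0.0)        { pre = dX; tb = 2; }
      else if (dY >= 0.0)                    { pre = dY; tb = 3; }
      M(i, j) = sub + pre;
      tbM(i, j) = tb;

      double xo = M(i - 1, j) - gap_open, xe = X(i - 1, j) - gap_extend;
      X(i, j) = (xo >= xe) ? xo : xe;
      double yo = M(i, j - 1) - gap_open, ye = Y(i, j - 1) - gap_extend;
      Y(i, j) = (yo >= ye) ? yo : ye;

      if (M(i, j) > best) { best = M(i, j); bi = i; bj = j; }
    }
  }

  std::vector<int> cols, qpos;
  if (best > 0.0) {
    int i = bi, j = bj; char state = 'M';
    while (i > 0 && j > 0) {
      if (state == 'M') {
        cols.push_back(i); qpos.push_back(j);
        int tb = tbM(i, j);
        --i; --j;
        if (tb == 0) break;
        state = (tb == 1) ? 'M' : (tb == 2) ? 'X' : 'Y';
      } else if (state == 'X') {
        // gap in query: decide whether X(i,j) opened here or extended
        if (M(i - 1, j) - gap_open >= X(i - 1, j) - gap_extend) state = 'M';
        --i;
      } else {  // Y: gap in profile
        if (M(i, j - 1) - gap_open >= Y(i, j - 1) - gap_extend) state = 'M';
        --j;
      }
    }
    std::reverse(cols.begin(), cols.end());
    std::reverse(qpos.begin(), qpos.end());
  }

  return List::create(_["score"] = best,
                      _["columns"] = wrap(cols),
                      _["positions"] = wrap(qpos));
}

// Pairwise local alignment of two integer-encoded sequences under a
// substitution matrix (alphabet x alphabet).  Unknown residues (code 0)
// score 0 against everything.  Returns the optimal score and the aligned
// span in both sequences (1-based; zeros when the score is 0).
// [[Rcpp::export(name = ".pair_sw_cpp")]]
List pair_sw_cpp(IntegerVector a, IntegerVector b, NumericMatrix sub,
                 double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  const int A = sub.nrow();

  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  IntegerMatrix tbM(n + 1, m + 1);
  for (int j = 0; j <= m; ++j) { X(0, j) = NEG_INF; Y(0, j) = NEG_INF; }
  for (int i = 0; i <= n; ++i) { X(i, 0) = NEG_INF; Y(i, 0) = NEG_INF; }

  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    int ca = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      int cb = b[j - 1];
      double s = 0.0;
      if (ca >= 1 && ca <= A && cb >= 1 && cb <= A) s = sub(ca - 1, cb - 1);

      double dM = M(i - 1, j - 1), dX = X(i - 1, j - 1), dY = Y(i - 1, j - 1);
      double pre = 0.0; int tb = 0;
      if (dM >= dX && dM >= dY && dM >= 0.0) { pre = dM; tb = 1; }
      else if (dX >= dY && dX >= 0.0)        { pre = dX; tb = 2; }
      else if (dY >= 0.0)                    { pre = dY; tb = 3; }
      M(i, j) = s + pre;
      tbM(i, j) = tb;

      double xo = M(i - 1, j) - gap_open, xe = X(i - 1, j) - gap_extend;
      X(i, j) = (xo >= xe) ? xo : xe;
      double yo = M(i, j - 1) - gap_open, ye = Y(i, j - 1) - gap_extend;
      Y(i, j) = (yo >= ye) ? yo : ye;

      if (M(i, j) > best) { best = M(i, j); bi = i; bj = j; }
    }
  }

  int a_start = 0, a_end = 0, b_start = 0, b_end = 0;
  if (best > 0.0) {
    a_end = bi; b_end = bj;
    int i = bi, j = bj; char state = 'M';
    a_start = i; b_start = j;
    while (i > 0 && j > 0) {
      if (state == 'M') {
        a_start = i; b_start = j;
        int tb = tbM(i, j);
        --i; --j;
        if (tb == 0) break;
        state = (tb == 1) ? 'M' : (tb == 2) ? 'X' : 'Y';
      } else if (state == 'X') {
        if (M(i - 1, j) - gap_open >= X(i - 1, j) - gap_extend) state = 'M';
        --i;
      } else {
        if (M(i, j - 1) - gap_open >= Y(i, j - 1) - gap_extend) state = 'M';
        --j;
      }
    }
  }

  return List::create(_["score"] = best,
                      _["a_start"] = a_start, _["a_end"] = a_end,
                      _["b_start"] = b_start, _["b_end"] = b_end);
}

// Score-only batch search: one query against a list of integer-encoded
// reference sequences.  Rolling-row affine-gap local DP, no traceback.
// [[Rcpp::export(name = ".search_scores_cpp")]]
NumericVector search_scores_cpp(IntegerVector q, List refs,
                                NumericMatrix sub,
                                double gap_open, double gap_extend) {
  const int m = q.size();
  const int A = sub.nrow();
  const int R = refs.size();
  NumericVector out(R);

  std::vector<double> Mp(m + 1), Mc(m + 1), Xp(m + 1), Xc(m + 1),
      Yp(m + 1), Yc(m + 1);
  for (int r = 0; r < R; ++r) {
    IntegerVector t = refs[r];
    const int n = t.size();
    double best = 0.0;
    std::fill(Mp.begin(), Mp.end(), 0.0);
    std::fill(Xp.begin(), Xp.end(), NEG_INF);
    std::fill(Yp.begin(), Yp.end(), NEG_INF);
    for (int i = 1; i <= n; ++i) {
      int ct = t[i - 1];
      Mc[0] = 0.0; Xc[0] = NEG_INF; Yc[0] = NEG_INF;
      for (int j = 1; j <= m; ++j) {
        int cq = q[j - 1];
        double s = 0.0;
        if (ct >= 1 && ct <= A && cq >= 1 && cq <= A) s = sub(ct - 1, cq - 1);
        double pre = 0.0;
        if (Mp[j - 1] > pre) pre = Mp[j - 1];
        if (Xp[j - 1] > pre) pre = Xp[j - 1];
        if (Yp[j - 1] > pre) pre = Yp[j - 1];
        Mc[j] = s + pre;
        double xo = Mp[j] - gap_open, xe = Xp[j] - gap_extend;
        Xc[j] = (xo >= xe) ? xo : xe;
        double yo = Mc[j - 1] - gap_open, ye = Yc[j - 1] - gap_extend;
        Yc[j] = (yo >= ye) ? yo : ye;
        if (Mc[j] > best) best = Mc[j];
      }
      std::swap(Mp, Mc);
      std::swap(Xp, Xc);
      std::swap(Yp, Yc);
    }
    out[r] = best;
  }
  return out;
}
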