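#include <Rcpp.h>
using namespace Rcpp;

// Gotoh global alignment with affine gaps over integer-coded sequences.
// a, b: 0-based indices into the scoring matrix `sub`.
// Gap of length k costs open + (k-1)*extend.
// Tie-break on traceback: match > delete (gap in b) > insert (gap in a).
// [[Rcpp::export(name = ".gotoh_align_cpp")]]
List gotoh_align_cpp(IntegerVector a, IntegerVector b, NumericMatrix sub,
                     double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  const double NEG = -1e30;
  // DP layers: M (a[i] aligned to b[j]), D (a[i] vs gap), I (gap vs b[j])
  NumericMatrix M(n + 1, m + 1), D(n + 1, m + 1), I(n + 1, m + 1);
  for (int i = 0; i <= n; ++i)
    for (int j = 0; j <= m; ++j) { M(i, j) = NEG; D(i, j) = NEG; I(i, j) = NEG; }
  M(0, 0) = 0.0;
  for (int i = 1; i <= n; ++i) D(i, 0) = -gap_open - (i - 1) * gap_extend;
  for (int j = 1; j <= m; ++j) I(0, j) = -gap_open - (j - 1) * gap_extend;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = sub(a[i - 1], b[j - 1]);
      double mm = std::max(M(i - 1, j - 1), std::max(D(i - 1, j - 1), I(i - 1, j - 1)));
      M(i, j) = mm + s;
      D(i, j) = std::max(M(i - 1, j) - gap_open, D(i - 1, j) - gap_extend);
      if (I(i - 1, j) - gap_open > D(i, j)) D(i, j) = I(i - 1, j) - gap_open;
      I(i, j) = std::max(M(i, j - 1) - gap_open, I(i, j - 1) - gap_extend);
      if (D(i, j - 1) - gap_open > I(i, j)) I(i, j) = D(i, j - 1) - gap_open;
    }
  }
  // traceback from best final layer, preference M > D > I
  int i = n, j = m, layer;
  double best = M(n, m); layer = 0;
  if (D(n, m) > best) { best = D(n, m); layer = 1; }
  if (I(n, m) > best) { best = I(n, m); layer = 2; }
  std::vector<int> ia, ib;
  while (i > 0 || j > 0) {
    if (layer == 0) {
      if (i == 0 || j == 0) { layer = (i > 0) ? 1 : 2; continue; }
      ia.push_back(a[i - 1]); ib.push_back(b[j - 1]);
      double prev = M(i, j) - sub(a[i - 1], b[j - 1]);
      // choose predecessor layer with tie-break M > D > I
      if (std::abs(M(i - 1, j - 1) - prev) < 1e-9) layer = 0;
      else if (std::abs(D(i - 1, j - 1) - prev) < 1e-9) layer = 1;
      else layer = 2;
      --i; --j;
    } else if (layer == 1) {
      ia.push_back(a[i - 1]); ib.push_back(-1);
      if (i > 1 || j > 0) {
        if (std::abs(M(i - 1, j) - gap_open - D(i, j)) < 1e-9) layer = 0;
        else if (std::abs(D(i - 1, j) - gap_extend - D(i, j)) < 1e-9) layer = 1;
        else layer = 2;
      }
      --i;
    } else {
      ia.push_back(-1); ib.push_back(b[j - 1]);
      if (j > 1 || i > 0) {
        if (std::abs(M(i, j - 1) - gap_open - I(i, j)) < 1e-9) layer = 0;
        else if (std::abs(I(i, j - 1) - gap_extend - I(i, j)) < 1e-9) layer = 2;
        else layer = 1;
      }
      --j;
    }
  }
  std::reverse(ia.begin(), ia.end());
  std::reverse(ib.begin(), ib.end());
  return List::create(_["a"] = wrap(ia), _["b"] = wrap(ib), _["score"] = best);
}

// Profile-profile affine alignment for progressive MSA.
// pa: K x m counts (K = alphabet size, gaps excluded from counts),
// pb: K x n. Column score = sum_xy pa[x,i]*pb[y,j]*sub[x,y] / (wa*wb),
// where wa, wb are the row counts (number of sequences) in each profile.
// Returns 0/1 gap masks for each profile's columns along the merged alignment.
// [[Rcpp::export(name = ".profile_align_cpp")]]
List profile_align_cpp(NumericMatrix pa, NumericMatrix pb, NumericMatrix sub,
                       double wa, double wb, double gap_open, double gap_extend) {
  const int K = pa.nrow();
  const int n = pa.ncol(), m = pb.ncol();
  NumericMatrix S(n, m);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j) {
      double s = 0.0;
      for (int x = 0; x < K; ++x) {
        if (pa(x, i) == 0) continue;
        for (int y = 0; y < K; ++y)
          if (pb(y, j) != 0) s += pa(x, i) * pb(y, j) * sub(x, y);
      }
      S(i, j) = s / (wa * wb);
    }
  const double NEG = -1e30;
  NumericMatrix M(n + 1, m + 1), D(n + 1, m + 1), I(n + 1, m + 1);
  for (int i = 0; i <= n; ++i)
    for (int j = 0; j <= m; ++j) { M(i, j) = NEG; D(i, j) = NEG; I(i, j) = NEG; }
  M(0, 0) = 0.0;
  for (int i = 1; i <= n; ++i) D(i, 0) = -gap_open - (i - 1) * gap_extend;
  for (int j = 1; j <= m; ++j) I(0, j) = -gap_open - (j - 1) * gap_extend;
  for (int i = 1; i <= n; ++i)
    for (int j = 1; j <= m; ++j) {
      double mm = std::max(M(i - 1, j - 1), std::max(D(i - 1, j - 1), I(i - 1, j - 1)));
      M(i, j) = mm + S(i - 1, j - 1);
      D(i, j) = std::max(M(i - 1, j) - gap_open, D(i - 1, j) - gap_extend);
      if (I(i - 1, j) - gap_open > D(i, j)) D(i, j) = I(i - 1, j) - gap_open;
      I(i, j) = std::max(M(i, j - 1) - gap_open, I(i, j - 1) - gap_extend);
      if (D(i, j - 1) - gap_open > I(i, j)) I(i, j) = D(i, j - 1) - gap_open;
    }
  int i = n, j = m, layer = 0;
  double best = M(n, m);
  if (D(n, m) > best) { best = D(n, m); layer = 1; }
  if (I(n, m) > best) { best = I(n, m); layer = 2; }
  std::vector<int> ga, gb; // 1 = column from this profile, 0 = gap
  while (i > 0 || j > 0) {
    if (layer == 0) {
      if (i == 0 || j == 0) { layer = (i > 0) ? 1 : 2; continue; }
      ga.push_back(1); gb.push_back(1);
      double prev = M(i, j) - S(i - 1, j - 1);
      if (std::abs(M(i - 1, j - 1) - prev) < 1e-9) layer = 0;
      else if (std::abs(D(i - 1, j - 1) - prev) < 1e-9) layer = 1;
      else layer = 2;
      --i; --j;
    } else if (layer == 1) {
      ga.push_back(1); gb.push_back(0);
      if (i > 1 || j > 0) {
        if (std::abs(M(i - 1, j) - gap_open - D(i, j)) < 1e-9) layer = 0;
        else if (std::abs(D(i - 1, j) - gap_extend - D(i, j)) < 1e-9) layer = 1;
        else layer = 2;
      }
      --i;
    } else {
      ga.push_back(0); gb.push_back(1);
      if (j > 1 || i > 0) {
        if (std::abs(M(i, j - 1) - gap_open - I(i, j)) < 1e-9) layer = 0;
        else if (std::abs(I(i, j - 1) - gap_extend - I(i, j)) < 1e-9) layer = 2;
        else layer = 1;
      }
      --j;
    }
  }
  std::reverse(ga.begin(), ga.end());
  std::reverse(gb.begin(), gb.end());
  return List::create(_["a"] = wrap(ga), _["b"] = wrap(gb), _["score"] = best);
}
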