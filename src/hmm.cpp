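#include <Rcpp.h>
using namespace Rcpp;

// Uni-local ("match anywhere") profile-HMM scoring in log2-odds space.
// lom, loi: L x n matrices of per-state, per-residue emission log-odds
// (log2 emission/background); insert rows beyond L-1 are ignored.
// lt: L x 7 log2 transition probabilities, columns MM MI MD IM II DM DD,
// row i = transitions out of node i (towards node i+1).
// Entry to any match state and exit from any match state are free;
// flanking residues score 0 (background).

static const double NEGINF = -1.0e300;

static inline double lse2(double a, double b) {
  if (a < -1.0e290) return b;
  if (b < -1.0e290) return a;
  double hi = a > b ? a : b, lo = a > b ? b : a;
  return hi + std::log2(1.0 + std::exp2(lo - hi));
}

// [[Rcpp::export(name = ".hmm_viterbi_cpp")]]
List hmm_viterbi_cpp(NumericMatrix lom, NumericMatrix loi, NumericMatrix lt) {
  const int L = lom.nrow(), n = lom.ncol();
  NumericMatrix VM(L + 1, n + 1), VI(L + 1, n + 1), VD(L + 1, n + 1);
  IntegerMatrix PM(L + 1, n + 1), PI(L + 1, n + 1), PD(L + 1, n + 1);
  std::fill(VM.begin(), VM.end(), NEGINF);
  std::fill(VI.begin(), VI.end(), NEGINF);
  std::fill(VD.begin(), VD.end(), NEGINF);
  // predecessor codes: 0 entry, 1 M, 2 I, 3 D
  for (int k = 1; k <= n; ++k) {
    for (int i = 1; i <= L; ++i) {
      double best = 0.0; int arg = 0; // free entry
      if (i > 1 && k > 1) {
        double v = VM(i - 1, k - 1) + lt(i - 2, 0);
        if (v > best) { best = v; arg = 1; }
        v = VI(i - 1, k - 1) + lt(i - 2, 3);
        if (v > best) { best = v; arg = 2; }
      }
      if (i > 1) {
        double v = VD(i - 1, k - 1) + lt(i - 2, 5);
        if (k > 1 && v > best) { best = v; arg = 3; }
      }
      VM(i, k) = lom(i - 1, k - 1) + best;
      PM(i, k) = arg;
      if (i < L) {
        double v1 = VM(i, k - 1) + lt(i - 1, 1);
        double v2 = VI(i, k - 1) + lt(i - 1, 4);
        if (v1 >= v2) { VI(i, k) = loi(i - 1, k - 1) + v1; PI(i, k) = 1; }
        else          { VI(i, k) = loi(i - 1, k - 1) + v2; PI(i, k) = 2; }
      }
      if (i > 1) {
        double v1 = VM(i - 1, k) + lt(i - 2, 2);
        double v2 = VD(i - 1, k) + lt(i - 2, 6);
        if (v1 >= v2) { VD(i, k) = v1; PD(i, k) = 1; }
        else          { VD(i, k) = v2; PD(i, k) = 3; }
      }
    }
  }
  double best = NEGINF; int bi = 1, bk = 1;
  for (int i = 1; i <= L; ++i)
    for (int k = 1; k <= n; ++k)
      if (VM(i, k) > best) { best = VM(i, k); bi = i; bk = k; }
  // traceback for envelope and state path
  std::string path;
  int i = bi, k = bk, st = 1; // st: 1 M, 2 I, 3 D
  int env_start = bk;
  while (true) {
    int prev;
    if (st == 1) { path.push_back('M'); env_start = k; prev = PM(i, k); --i; --k; }
    else if (st == 2) { path.push_back('I'); prev = PI(i, k); --k; }
    else { path.push_back('D'); prev = PD(i, k); --i; }
    if (st == 1 && prev == 0) break;
    st = prev;
  }
  std::reverse(path.begin(), path.end());
  return List::create(_["score"] = best, _["env_start"] = env_start,
                      _["env_end"] = bk, _["exit_state"] = bi,
                      _["path"] = path);
}

// [[Rcpp::export(name = ".hmm_forward_cpp")]]
double hmm_forward_cpp(NumericMatrix lom, NumericMatrix loi, NumericMatrix lt) {
  const int L = lom.nrow(), n = lom.ncol();
  NumericMatrix FM(L + 1, n + 1), FI(L + 1, n + 1), FD(L + 1, n + 1);
  std::fill(FM.begin(), FM.end(), NEGINF);
  std::fill(FI.begin(), FI.end(), NEGINF);
  std::fill(FD.begin(), FD.end(), NEGINF);
  double total = NEGINF;
  for (int k = 1; k <= n; ++k) {
    for (int i = 1; i <= L; ++i) {
      double acc = 0.0; // free entry path
      if (i > 1 && k > 1) {
        acc = lse2(acc, FM(i - 1, k - 1) + lt(i - 2, 0));
        acc = lse2(acc, FI(i - 1, k - 1) + lt(i - 2, 3));
        acc = lse2(acc, FD(i - 1, k - 1) + lt(i - 2, 5));
      }
      FM(i, k) = lom(i - 1, k - 1) + acc;
      if (i < L)
        FI(i, k) = loi(i - 1, k - 1) +
          lse2(FM(i, k - 1) + lt(i - 1, 1), FI(i, k - 1) + lt(i - 1, 4));
      if (i > 1)
        FD(i, k) = lse2(FM(i - 1, k) + lt(i - 2, 2), FD(i - 1, k) + lt(i - 2, 6));
      total = lse2(total, FM(i, k)); // exit free from any match state
    }
  }
  return total;
}
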