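#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap global alignment (Gotoh three-state recursion) over a
// precomputed column-score matrix S, where S(i,j) is the score of pairing
// unit i of sequence/profile A with unit j of B. Gap of length k costs
// gap_open + (k - 1) * gap_extend. Traceback tie-break: diagonal > up
// (gap in B) > left (gap in A), and within a state M > X > Y, so the
// alignment is deterministic.
//
// Returns list(score, a_idx, b_idx) where a_idx/b_idx are 1-based unit
// indices per alignment column, 0 marking a gap.
// [[Rcpp::export]]
List gotoh_align_cpp(NumericMatrix S, double gap_open, double gap_extend) {
  const int n = S.nrow(), m = S.ncol();
  const double NEG = -1e18;
  // state 0 = M (match), 1 = X (gap in B, consume A), 2 = Y (gap in A)
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  M(0, 0) = 0.0; X(0, 0) = NEG; Y(0, 0) = NEG;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG; Y(i, 0) = NEG;
    X(i, 0) = -gap_open - (i - 1) * gap_extend;
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG; X(0, j) = NEG;
    Y(0, j) = -gap_open - (j - 1) * gap_extend;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double prev = std::max(M(i - 1, j - 1),
                             std::max(X(i - 1, j - 1), Y(i - 1, j - 1)));
      M(i, j) = prev + S(i - 1, j - 1);
      X(i, j) = std::max(M(i - 1, j) - gap_open,
                         std::max(X(i - 1, j) - gap_extend,
                                  Y(i - 1, j) - gap_open));
      Y(i, j) = std::max(M(i, j - 1) - gap_open,
                         std::max(X(i, j - 1) - gap_open,
                                  Y(i, j - 1) - gap_extend));
    }
  }

  int i = n, j = m, state;
  double score;
  // preference M > X > Y on exact ties
  if (M(n, m) >= X(n, m) && M(n, m) >= Y(n, m)) { state = 0; score = M(n, m); }
  else if (X(n, m) >= Y(n, m))                  { state = 1; score = X(n, m); }
  else                                          { state = 2; score = Y(n, m); }

  std::vector<int> ai, bi;
  while (i > 0 || j > 0) {
    if (state == 0) {
      ai.push_back(i); bi.push_back(j);
      double tgt = M(i, j) - S(i - 1, j - 1);
      --i; --j;
      if (M(i, j) >= tgt - 1e-9)      state = 0;
      else if (X(i, j) >= tgt - 1e-9) state = 1;
      else                            state = 2;
    } else if (state == 1) {
      ai.push_back(i); bi.push_back(0);
      double v = X(i, j);
      --i;
      if (i == 0 && j == 0) break;
      if (M(i, j) - gap_open >= v - 1e-9)        state = 0;
      else if (X(i, j) - gap_extend >= v - 1e-9) state = 1;
      else                                       state = 2;
    } else {
      ai.push_back(0); bi.push_back(j);
      double v = Y(i, j);
      --j;
      if (i == 0 && j == 0) break;
      if (M(i, j) - gap_open >= v - 1e-9)        state = 0;
      else if (X(i, j) - gap_open >= v - 1e-9)   state = 1;
      else                                       state = 2;
    }
    if (i == 0 && j == 0) break;
    if (i == 0) state = 2;
    if (j == 0) state = 1;
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
  return List::create(_["score"] = score,
                      _["a_idx"] = wrap(ai),
                      _["b_idx"] = wrap(bi));
}
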