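#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with affine gap costs over a
// precomputed column-pair score matrix. sm(i, j) is the score of aligning
// column i of profile A against column j of profile B. A gap run of length
// k costs gap_open + k * gap_extend (both <= 0). End gaps are penalized.
//
// Returns the optimal score and the aligned column paths: integer vectors
// over {0, 1..L} where 0 marks a gap in that profile. Ties are resolved in
// the fixed order match > gap-in-B > gap-in-A so results are deterministic.
// [[Rcpp::export(name = ".nw_affine")]]
List nw_affine(NumericMatrix sm, double gap_open, double gap_extend) {
  const int la = sm.nrow();
  const int lb = sm.ncol();
  const double NEG = -1e30;

  // DP matrices: M ends in a match, X ends with gap in B (consumes A),
  // Y ends with gap in A (consumes B)
  NumericMatrix M(la + 1, lb + 1), X(la + 1, lb + 1), Y(la + 1, lb + 1);
  IntegerMatrix tM(la + 1, lb + 1), tX(la + 1, lb + 1), tY(la + 1, lb + 1);

  M(0, 0) = 0.0; X(0, 0) = NEG; Y(0, 0) = NEG;
  for (int i = 1; i <= la; ++i) {
    M(i, 0) = NEG;
    X(i, 0) = gap_open + i * gap_extend;
    Y(i, 0) = NEG;
    tX(i, 0) = 1; // came from X
  }
  for (int j = 1; j <= lb; ++j) {
    M(0, j) = NEG;
    X(0, j) = NEG;
    Y(0, j) = gap_open + j * gap_extend;
    tY(0, j) = 2; // came from Y
  }

  for (int i = 1; i <= la; ++i) {
    for (int j = 1; j <= lb; ++j) {
      // M: align column i of A with column j of B
      double bm = M(i - 1, j - 1); int sm_tr = 0;
      if (X(i - 1, j - 1) > bm) { bm = X(i - 1, j - 1); sm_tr = 1; }
      if (Y(i - 1, j - 1) > bm) { bm = Y(i - 1, j - 1); sm_tr = 2; }
      M(i, j) = bm + sm(i - 1, j - 1);
      tM(i, j) = sm_tr;

      // X: gap in B against column i of A
      double open_x = M(i - 1, j) + gap_open + gap_extend;
      double ext_x  = X(i - 1, j) + gap_extend;
      double oy_x   = Y(i - 1, j) + gap_open + gap_extend;
      double bx = open_x; int tx = 0;
      if (ext_x > bx) { bx = ext_x; tx = 1; }
      if (oy_x > bx)  { bx = oy_x;  tx = 2; }
      X(i, j) = bx; tX(i, j) = tx;

      // Y: gap in A against column j of B
      double open_y = M(i, j - 1) + gap_open + gap_extend;
      double ox_y   = X(i, j - 1) + gap_open + gap_extend;
      double ext_y  = Y(i, j - 1) + gap_extend;
      double by = open_y; int ty = 0;
      if (ox_y > by) { by = ox_y; ty = 1; }
      if (ext_y > by) { by = ext_y; ty = 2; }
      Y(i, j) = by; tY(i, j) = ty;
    }
  }

  double score = M(la, lb); int state = 0;
  if (X(la, lb) > score) { score = X(la, lb); state = 1; }
  if (Y(la, lb) > score) { score = Y(la, lb); state = 2; }

  std::vector<int> pa, pb;
  int i = la, j = lb;
  while (i > 0 || j > 0) {
    if (state == 0) {
      int prev = tM(i, j);
      pa.push_back(i); pb.push_back(j);
      --i; --j;
      state = prev;
    } else if (state == 1) {
      int prev = tX(i, j);
      pa.push_back(i); pb.push_back(0);
      --i;
      state = prev;
    } else {
      int prev = tY(i, j);
      pa.push_back(0); pb.push_back(j);
      --j;
      state = prev;
    }
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());

  return List::create(_["score"] = score,
                      _["path_a"] = IntegerVector(pa.begin(), pa.end()),
                      _["path_b"] = IntegerVector(pb.begin(), pb.end()));
}
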