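// Affine-gap global alignment of a nucleotide sequence against an alignment
// profile (Gotoh three-state DP), the kernel of the builtin progressive
// aligner.  Residue codes: 0..3 = A,C,G,T; 4 = other (always a mismatch);
// profile rows: counts of A,C,G,T,other,gap per column.
//
// Returned op codes, left to right:
//   0 = consume one profile column and one residue (diagonal)
//   1 = consume one profile column only (gap in the new sequence)
//   2 = consume one residue only (a new all-gap column in the profile)

#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export(name = ".profile_align_cpp")]]
IntegerVector profile_align_cpp(IntegerMatrix prof, IntegerVector seq,
                                double match, double mismatch,
                                double gap_open, double gap_extend) {
  const int W = prof.ncol();    // profile columns
  const int L = seq.size();     // residues
  if (prof.nrow() != 6) stop("profile must have 6 rows");

  // rows represented by the profile (counts in any column sum to it)
  double nrows = 1.0;
  if (W > 0) {
    nrows = 0.0;
    for (int r = 0; r < 6; ++r) nrows += prof(r, 0);
    if (nrows <= 0) nrows = 1.0;
  }

  std::vector<double> colscore((size_t)W * 5, 0.0);
  for (int j = 0; j < W; ++j) {
    for (int r = 0; r < 5; ++r) {
      double s = 0.0;
      for (int x = 0; x < 5; ++x) {
        double cnt = prof(x, j);
        if (cnt == 0) continue;
        s += cnt * ((x == r && r < 4) ? match : mismatch);
      }
      s += prof(5, j) * gap_extend;  // gaps in the profile column
      colscore[(size_t)j * 5 + r] = s / nrows;
    }
  }

  // H: best ending in diagonal; U: ending with gap in sequence (column
  // consumed); V: ending with gap column in profile (residue consumed)
  const size_t nc = (size_t)(W + 1) * (L + 1);
  std::vector<double> H(nc), U(nc), V(nc);
  std::vector<unsigned char> tbH(nc), tbU(nc), tbV(nc);
  auto ix = [&](int i, int j) { return (size_t)i * (L + 1) + j; };

  H[ix(0, 0)] = 0.0;
  U[ix(0, 0)] = V[ix(0, 0)] = NEG_INF;
  for (int i = 1; i <= W; ++i) {
    U[ix(i, 0)] = gap_open + gap_extend * i;
    H[ix(i, 0)] = U[ix(i, 0)];
    V[ix(i, 0)] = NEG_INF;
    tbU[ix(i, 0)] = 1;  // came from U
  }
  for (int j = 1; j <= L; ++j) {
    V[ix(0, j)] = gap_open + gap_extend * j;
    H[ix(0, j)] = V[ix(0, j)];
    U[ix(0, j)] = NEG_INF;
    tbV[ix(0, j)] = 1;
  }

  for (int i = 1; i <= W; ++i) {
    const double* cs = &colscore[(size_t)(i - 1) * 5];
    for (int j = 1; j <= L; ++j) {
      const int r = seq[j - 1];
      // U: consume column i (gap in sequence)
      double u_open = H[ix(i - 1, j)] + gap_open + gap_extend;
      double u_ext  = U[ix(i - 1, j)] + gap_extend;
      if (u_ext > u_open) { U[ix(i, j)] = u_ext; tbU[ix(i, j)] = 1; }
      else               { U[ix(i, j)] = u_open; tbU[ix(i, j)] = 0; }
      // V: consume residue j (gap column in profile)
      double v_open = H[ix(i, j - 1)] + gap_open + gap_extend;
      double v_ext  = V[ix(i, j - 1)] + gap_extend;
      if (v_ext > v_open) { V[ix(i, j)] = v_ext; tbV[ix(i, j)] = 1; }
      else               { V[ix(i, j)] = v_open; tbV[ix(i, j)] = 0; }
      // H: best of diagonal, U, V (prefer diagonal, then U, then V)
      double d = H[ix(i - 1, j - 1)] + cs[r];
      double best = d; unsigned char tb = 0;
      if (U[ix(i, j)] > best) { best = U[ix(i, j)]; tb = 1; }
      if (V[ix(i, j)] > best) { best = V[ix(i, j)]; tb = 2; }
      H[ix(i, j)] = best; tbH[ix(i, j)] = tb;
    }
  }

  // traceback
  std::vector<int> ops;
  ops.reserve(W + L);
  int i = W, j = L, state = 0;  // 0 = H, 1 = U, 2 = V
  if (W == 0 && L == 0) { /* empty */ }
  while (i > 0 || j > 0) {
    if (state == 0) {
      if (i == 0) { state = 2; continue; }
      if (j == 0) { state = 1; continue; }
      unsigned char tb = tbH[ix(i, j)];
      if (tb == 0) { ops.push_back(0); --i; --j; }
      else state = tb;  // 1 -> U, 2 -> V
    } else if (state == 1) {
      ops.push_back(1);
      unsigned char tb = tbU[ix(i, j)];
      --i;
      state = (tb == 1) ? 1 : 0;
    } else {
      ops.push_back(2);
      unsigned char tb = tbV[ix(i, j)];
      --j;
      state = (tb == 1) ? 2 : 0;
    }
  }
  std::reverse(ops.begin(), ops.end());
  return wrap(ops);
}
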