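#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <climits>
#include <algorithm>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps.
// A gap of length k costs gap_open + k * gap_extend (BLAST-style existence
// plus per-residue cost). Sequences arrive as 0-based integer codes indexing
// the substitution matrix.
//
// Tie-breaking is fixed so traces are reproducible: when scores tie, the
// trace prefers diagonal, then up (gap in the second sequence), then left.
// The traceback start cell is the first maximal cell in row-major order.

static inline int imax2c(int a, int b) { return a > b ? a : b; }

// Raw-buffer scoring kernel. mat_rm is the substitution matrix in row-major
// layout (row = first-sequence code), nm its dimension. H/F are scratch
// buffers of length m+1 (overwritten).
static int sw_score_raw(const int* a, int n, const int* b, int m,
                        const int* mat_rm, int nm, int go, int ge,
                        int* H, int* F) {
  const int NEG = INT_MIN / 4;
  for (int j = 0; j <= m; ++j) { H[j] = 0; F[j] = NEG; }
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    const int* Mrow = mat_rm + (size_t)a[i - 1] * nm;
    int E = NEG, Hdiag = H[0];
    for (int j = 1; j <= m; ++j) {
      const int e1 = H[j - 1] - go, e2 = E - ge;
      E = e1 > e2 ? e1 : e2;
      const int f1 = H[j] - go, f2 = F[j] - ge;
      const int f = f1 > f2 ? f1 : f2;
      F[j] = f;
      int h = Hdiag + Mrow[b[j - 1]];
      if (E > h) h = E;
      if (f > h) h = f;
      if (h < 0) h = 0;
      Hdiag = H[j];
      H[j] = h;
      if (h > best) best = h;
    }
  }
  return best;
}

// [[Rcpp::export(name = ".sw_score_c")]]
int sw_score_c(IntegerVector a, IntegerVector b, IntegerMatrix mat,
               int gap_open, int gap_extend) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) return 0;
  const int nm = mat.nrow();
  std::vector<int> mat_rm((size_t)nm * nm);
  for (int r = 0; r < nm; ++r)
    for (int c = 0; c < nm; ++c) mat_rm[(size_t)r * nm + c] = mat(r, c);
  std::vector<int> H(m + 1), F(m + 1);
  return sw_score_raw(a.begin(), n, b.begin(), m, mat_rm.data(), nm,
                      gap_open + gap_extend, gap_extend, H.data(), F.data());
}

// All-vs-all local alignment scores; rows = queries, cols = targets.
// [[Rcpp::export(name = ".sw_score_matrix_c")]]
IntegerMatrix sw_score_matrix_c(List a, List b, IntegerMatrix mat,
                                int gap_open, int gap_extend) {
  const int na = a.size(), nb = b.size();
  const int nm = mat.nrow();
  std::vector<int> mat_rm((size_t)nm * nm);
  for (int r = 0; r < nm; ++r)
    for (int c = 0; c < nm; ++c) mat_rm[(size_t)r * nm + c] = mat(r, c);
  IntegerMatrix out(na, nb);
  std::vector<IntegerVector> bv(nb);
  int maxm = 1;
  for (int j = 0; j < nb; ++j) {
    bv[j] = as<IntegerVector>(b[j]);
    if (bv[j].size() > maxm) maxm = bv[j].size();
  }
  std::vector<int> H(maxm + 1), F(maxm + 1);
  const int go = gap_open + gap_extend;
  for (int i = 0; i < na; ++i) {
    IntegerVector ai = as<IntegerVector>(a[i]);
    for (int j = 0; j < nb; ++j)
      out(i, j) = sw_score_raw(ai.begin(), ai.size(), bv[j].begin(),
                               bv[j].size(), mat_rm.data(), nm, go,
                               gap_extend, H.data(), F.data());
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// Full alignment with traceback. Returns 0-based half-open intervals and the
// per-column residue indices of each sequence (-1 marks a gap column).
// [[Rcpp::export(name = ".sw_align_c")]]
List sw_align_c(IntegerVector a, IntegerVector b, IntegerMatrix mat,
                int gap_open, int gap_extend) {
  const int n = a.size(), m = b.size();
  const int go = gap_open + gap_extend, ge = gap_extend;
  const int NEG = INT_MIN / 4;
  // pointer codes for H: 0 stop, 1 diag, 2 up (F), 3 left (E)
  // for E/F: 0 opened from H, 1 extended
  const int nm = mat.nrow();
  std::vector<int> mat_rm((size_t)nm * nm);
  for (int r = 0; r < nm; ++r)
    for (int c = 0; c < nm; ++c) mat_rm[(size_t)r * nm + c] = mat(r, c);
  const int* bc = b.begin();
  std::vector<uint8_t> ptrH((size_t)(n + 1) * (m + 1), 0);
  std::vector<uint8_t> ptrE((size_t)(n + 1) * (m + 1), 0);
  std::vector<uint8_t> ptrF((size_t)(n + 1) * (m + 1), 0);
  std::vector<int> H(m + 1, 0), F(m + 1, NEG);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    const int* Mrow = mat_rm.data() + (size_t)a[i - 1] * nm;
    uint8_t* pH = ptrH.data() + (size_t)i * (m + 1);
    uint8_t* pE = ptrE.data() + (size_t)i * (m + 1);
    uint8_t* pF = ptrF.data() + (size_t)i * (m + 1);
    int Ecur = NEG, Hdiag = H[0];
    for (int j = 1; j <= m; ++j) {
      const int e_open = H[j - 1] - go, e_ext = Ecur - ge;
      if (e_open >= e_ext) { Ecur = e_open; pE[j] = 0; }
      else                 { Ecur = e_ext;  pE[j] = 1; }
      const int f_open = H[j] - go, f_ext = F[j] - ge;
      if (f_open >= f_ext) { F[j] = f_open; pF[j] = 0; }
      else                 { F[j] = f_ext;  pF[j] = 1; }
      const int diag = Hdiag + Mrow[bc[j - 1]];
      // priority on ties: diag > up > left > stop
      int h = diag; uint8_t p = 1;
      if (F[j] > h) { h = F[j]; p = 2; }
      if (Ecur > h) { h = Ecur; p = 3; }
      if (h <= 0)   { h = 0;    p = 0; }
      Hdiag = H[j];
      H[j] = h; pH[j] = p;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  std::vector<int> acol, bcol;
  int i = bi, j = bj;
  if (best > 0) {
    int state = 0;  // 0 = H, 1 = E (left), 2 = F (up)
    while (true) {
      const size_t idx = (size_t)i * (m + 1) + j;
      if (state == 0) {
        uint8_t p = ptrH[idx];
        if (p == 0) break;
        if (p == 1) { acol.push_back(i - 1); bcol.push_back(j - 1); --i; --j; }
        else if (p == 2) state = 2;
        else state = 1;
      } else if (state == 1) {  // gap in a, consume b
        uint8_t p = ptrE[idx];
        acol.push_back(-1); bcol.push_back(j - 1); --j;
        if (p == 0) state = 0;
      } else {  // gap in b, consume a
        uint8_t p = ptrF[idx];
        acol.push_back(i - 1); bcol.push_back(-1); --i;
        if (p == 0) state = 0;
      }
    }
  }
  std::reverse(acol.begin(), acol.end());
  std::reverse(bcol.begin(), bcol.end());
  return List::create(_["score"] = best, _["a_start"] = i, _["a_end"] = bi,
                      _["b_start"] = j, _["b_end"] = bj,
                      _["a_col"] = wrap(acol), _["b_col"] = wrap(bcol));
}
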