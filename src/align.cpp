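#include <Rcpp.h>
#include <climits>
#include <vector>
using namespace Rcpp;

// Affine-gap pairwise alignment over integer-coded sequences.
// A gap of length L costs gapOpen + gapExt * L.
// Codes are 0-based row/column indices into `mat`.
//
// type: 0 = local (Smith-Waterman), 1 = global (Needleman-Wunsch),
//       2 = global in `a`, free end gaps in `b` ("glocal": a aligns
//           contiguously inside b).
//
// Traceback tie-break order: diagonal > up (gap in b) > left (gap in a).

static const int NEG = INT_MIN / 4;

// [[Rcpp::export]]
List cpp_pairwise_align(IntegerVector a, IntegerVector b, IntegerMatrix mat,
                        int gapOpen, int gapExt, int type, bool traceback) {
  const int n = a.size(), m = b.size();
  const int W = m + 1;
  std::vector<int> H((n + 1) * W, NEG), E((n + 1) * W, NEG), F((n + 1) * W, NEG);
  // pointers: pH: 0 stop, 1 diag, 2 up(F), 3 left(E); pE/pF: 1 open, 2 extend
  std::vector<unsigned char> pH, pE, pF;
  pH.assign((n + 1) * W, 0); pE.assign((n + 1) * W, 0); pF.assign((n + 1) * W, 0);

  H[0] = 0;
  for (int j = 1; j <= m; ++j) {
    if (type == 0 || type == 2) { H[j] = 0; }
    else { H[j] = -(gapOpen + gapExt * j); pH[j] = 3; }
    E[j] = (type == 1) ? H[j] : NEG;
  }
  for (int i = 1; i <= n; ++i) {
    int r = i * W;
    if (type == 0) H[r] = 0;
    else { H[r] = -(gapOpen + gapExt * i); pH[r] = 2; }
    F[r] = (type != 0) ? H[r] : NEG;
  }

  int best = (type == 0) ? 0 : NEG, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    const int ai = a[i - 1];
    int r = i * W, rp = (i - 1) * W;
    for (int j = 1; j <= m; ++j) {
      // E: gap in a (move left along b)
      int eOpen = (H[r + j - 1] == NEG) ? NEG : H[r + j - 1] - gapOpen - gapExt;
      int eExt  = (E[r + j - 1] == NEG) ? NEG : E[r + j - 1] - gapExt;
      if (eOpen >= eExt) { E[r + j] = eOpen; pE[r + j] = 1; }
      else               { E[r + j] = eExt;  pE[r + j] = 2; }
      // F: gap in b (move up along a)
      int fOpen = (H[rp + j] == NEG) ? NEG : H[rp + j] - gapOpen - gapExt;
      int fExt  = (F[rp + j] == NEG) ? NEG : F[rp + j] - gapExt;
      if (fOpen >= fExt) { F[r + j] = fOpen; pF[r + j] = 1; }
      else               { F[r + j] = fExt;  pF[r + j] = 2; }
      int diag = (H[rp + j - 1] == NEG) ? NEG : H[rp + j - 1] + mat(ai, b[j - 1]);
      // priority: diag > up > left (> stop for local)
      int h = diag; unsigned char p = 1;
      if (F[r + j] > h) { h = F[r + j]; p = 2; }
      if (E[r + j] > h) { h = E[r + j]; p = 3; }
      if (type == 0 && h <= 0) { h = 0; p = 0; }
      H[r + j] = h; pH[r + j] = p;
      if (type == 0 && h > best) { best = h; bi = i; bj = j; }
    }
  }

  if (type == 1) { best = H[n * W + m]; bi = n; bj = m; }
  else if (type == 2) {
    best = NEG;
    for (int j = 0; j <= m; ++j)
      if (H[n * W + j] > best) { best = H[n * W + j]; bi = n; bj = j; }
  }

  if (!traceback) {
    return List::create(_["score"] = best);
  }

  // traceback
  std::vector<int> aal, bal; // 1-based positions, 0 = gap
  int i = bi, j = bj;
  int state = 0; // 0 in H, 1 in E, 2 in F
  while (i > 0 || j > 0) {
    if (state == 0) {
      unsigned char p = pH[i * W + j];
      if (p == 0) break;                      // local start
      if (type == 2 && i == 0) break;         // free leading b gap
      if (p == 1) { aal.push_back(i); bal.push_back(j); --i; --j; }
      else if (p == 2) state = 2;
      else state = 1;
    } else if (state == 1) {                  // E: gap in a, consume b
      aal.push_back(0); bal.push_back(j);
      if (pE[i * W + j] == 1) state = 0;
      --j;
      if (type != 1 && i == 0) break;
    } else {                                  // F: gap in b, consume a
      aal.push_back(i); bal.push_back(0);
      if (pF[i * W + j] == 1) state = 0;
      --i;
    }
    if (type == 0 && state == 0 && pH[i * W + j] == 0 && i > 0 && j > 0 &&
        H[i * W + j] == 0) break;
  }
  std::reverse(aal.begin(), aal.end());
  std::reverse(bal.begin(), bal.end());

  int aStart = 0, aEnd = 0, bStart = 0, bEnd = 0;
  for (size_t k = 0; k < aal.size(); ++k) {
    if (aal[k] > 0) { if (!aStart) aStart = aal[k]; aEnd = aal[k]; }
    if (bal[k] > 0) { if (!bStart) bStart = bal[k]; bEnd = bal[k]; }
  }
  return List::create(_["score"] = best,
                      _["a_aln"] = wrap(aal), _["b_aln"] = wrap(bal),
                      _["a_start"] = aStart, _["a_end"] = aEnd,
                      _["b_start"] = bStart, _["b_end"] = bEnd);
}

// Score-only local alignment with O(m) memory, for oracle sweeps over
// long subjects.
// [[Rcpp::export]]
int cpp_local_score(IntegerVector a, IntegerVector b, IntegerMatrix mat,
                    int gapOpen, int gapExt) {
  const int n = a.size(), m = b.size();
  const int A = mat.ncol();
  std::vector<int> M(A * A);
  for (int r = 0; r < A; ++r)
    for (int c = 0; c < A; ++c) M[r * A + c] = mat(r, c);
  std::vector<int> bb(b.begin(), b.end());
  std::vector<int> H(m + 1, 0), Hd(m + 1, 0);
  std::vector<int> F(m + 1, NEG);
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    const int *Mrow = &M[a[i - 1] * A];
    Hd.swap(H);
    H[0] = 0; int Ei = NEG;
    for (int j = 1; j <= m; ++j) {
      int eOpen = H[j - 1] - gapOpen - gapExt;
      int eExt = (Ei == NEG) ? NEG : Ei - gapExt;
      Ei = eOpen > eExt ? eOpen : eExt;
      int fOpen = Hd[j] - gapOpen - gapExt;
      int fExt = (F[j] == NEG) ? NEG : F[j] - gapExt;
      F[j] = fOpen > fExt ? fOpen : fExt;
      int h = Hd[j - 1] + Mrow[bb[j - 1]];
      if (F[j] > h) h = F[j];
      if (Ei > h) h = Ei;
      if (h < 0) h = 0;
      H[j] = h;
      if (h > best) best = h;
    }
  }
  return best;
}
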