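#include <Rcpp.h>
#include <vector>
#include <map>
#include <algorithm>
#include <climits>
using namespace Rcpp;

// Seeded local similarity search (word neighborhood -> ungapped x-drop
// extension -> windowed gapped extension), the engine behind both the
// translated six-frame search and the nucleotide exclusion filter.
//
// Sequences are integer-coded (0-based codes indexing `mat`). Subjects are
// typically translated genome frames (protein) or database records (DNA).

static const int NEG = INT_MIN / 4;

// score-only forward pass returning best score and its end cell
static void local_best_end(const std::vector<int> &a, const std::vector<int> &b,
                           const IntegerMatrix &mat, int go, int ge,
                           int &best, int &bi, int &bj) {
  const int n = a.size(), m = b.size();
  std::vector<int> H(m + 1, 0), Hd(m + 1, 0), F(m + 1, NEG);
  best = 0; bi = 0; bj = 0;
  for (int i = 1; i <= n; ++i) {
    Hd.swap(H);
    H[0] = 0;
    int Ei = NEG;
    const int ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      int eOpen = H[j - 1] - go - ge;
      int eExt = (Ei == NEG) ? NEG : Ei - ge;
      Ei = eOpen > eExt ? eOpen : eExt;
      int fOpen = Hd[j] - go - ge;
      int fExt = (F[j] == NEG) ? NEG : F[j] - ge;
      F[j] = fOpen > fExt ? fOpen : fExt;
      int h = Hd[j - 1] + mat(ai, b[j - 1]);
      if (F[j] > h) h = F[j];
      if (Ei > h) h = Ei;
      if (h < 0) h = 0;
      H[j] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
}

// full local alignment coordinates via two score-only passes
static void local_align_coords(const std::vector<int> &a, const std::vector<int> &b,
                               const IntegerMatrix &mat, int go, int ge,
                               int &score, int &qs, int &qe, int &ss, int &se) {
  int bi, bj;
  local_best_end(a, b, mat, go, ge, score, bi, bj);
  if (score <= 0) { qs = qe = ss = se = 0; return; }
  qe = bi; se = bj;
  std::vector<int> ar(a.begin(), a.begin() + bi), br(b.begin(), b.begin() + bj);
  std::reverse(ar.begin(), ar.end());
  std::reverse(br.begin(), br.end());
  int s2, ri, rj;
  local_best_end(ar, br, mat, go, ge, s2, ri, rj);
  qs = bi - ri + 1; ss = bj - rj + 1;
}

// enumerate all words scoring >= thresh against the query word at position p
static void neighbors_dfs(const std::vector<int> &q, int p, int wordLen,
                          const IntegerMatrix &mat, int thresh, int A,
                          const std::vector<int> &rowmax,
                          std::vector<std::pair<int, long long> > &out) {
  std::vector<int> suf(wordLen + 1, 0);
  for (int k = wordLen - 1; k >= 0; --k) suf[k] = suf[k + 1] + rowmax[q[p + k]];
  std::vector<int> choice(wordLen, -1);
  std::vector<int> partial(wordLen + 1, 0);
  int k = 0;
  while (k >= 0) {
    if (k == wordLen) {
      long long id = 0;
      for (int t = 0; t < wordLen; ++t) id = id * A + choice[t];
      out.push_back(std::make_pair(p, id));
      --k;
      continue;
    }
    int r = ++choice[k];
    if (r >= A) { choice[k] = -1; --k; continue; }
    int sc = partial[k] + mat(q[p + k], r);
    if (sc + suf[k + 1] < thresh) continue;
    partial[k + 1] = sc;
    ++k;
  }
}

struct Hit { int query, subject, score, qs, qe, ss, se; };

// [[Rcpp::export]]
DataFrame cpp_seed_search(List queries, List subjects, IntegerMatrix mat,
                          int wordLen, int neighborThresh, int xDrop,
                          int gapOpen, int gapExt, int gapTrigger, int band,
                          int minReport) {
  const int A = mat.ncol();
  long long nWords = 1;
  for (int t = 0; t < wordLen; ++t) nWords *= A;

  const int nSub = subjects.size(), nQ = queries.size();
  std::vector<std::vector<int> > sub(nSub);
  for (int s = 0; s < nSub; ++s) {
    IntegerVector v = subjects[s];
    sub[s].assign(v.begin(), v.end());
  }
  std::vector<int> rowmax(A, NEG);
  for (int r = 0; r < A; ++r)
    for (int c = 0; c < A; ++c)
      if (mat(r, c) > rowmax[r]) rowmax[r] = mat(r, c);

  // CSR word index per subject
  std::vector<std::vector<int> > idxStart(nSub), idxPos(nSub);
  for (int s = 0; s < nSub; ++s) {
    const std::vector<int> &S = sub[s];
    const int L = (int)S.size() - wordLen + 1;
    idxStart[s].assign(nWords + 1, 0);
    if (L < 1) continue;
    std::vector<long long> wid(L);
    long long hi = 1;
    for (int t = 0; t < wordLen - 1; ++t) hi *= A;
    long long id = 0;
    for (int t = 0; t < wordLen; ++t) id = id * A + S[t];
    wid[0] = id;
    for (int p = 1; p < L; ++p) {
      id = (id - (long long)S[p - 1] * hi) * A + S[p + wordLen - 1];
      wid[p] = id;
    }
    for (int p = 0; p < L; ++p) idxStart[s][wid[p] + 1]++;
    for (long long w = 0; w < nWords; ++w) idxStart[s][w + 1] += idxStart[s][w];
    idxPos[s].resize(L);
    std::vector<int> fill(idxStart[s]);
    for (int p = 0; p < L; ++p) idxPos[s][fill[wid[p]]++] = p;
  }

  // flat copy of the matrix for fast access
  std::vector<int> M(A * A);
  for (int r = 0; r < A; ++r)
    for (int c = 0; c < A; ++c) M[r * A + c] = mat(r, c);

  // epoch-stamped per-diagonal coverage (avoids clearing between queries)
  int maxSlen = 0;
  for (int s = 0; s < nSub; ++s)
    if ((int)sub[s].size() > maxSlen) maxSlen = sub[s].size();
  int maxQlen = 0;
  for (int qi = 0; qi < nQ; ++qi) {
    IntegerVector qv = queries[qi];
    if (qv.size() > maxQlen) maxQlen = qv.size();
  }
  std::vector<int> covVal(maxSlen + maxQlen + 2, 0);
  std::vector<long long> covEpoch(maxSlen + maxQlen + 2, -1);

  std::vector<Hit> hits;
  for (int qi = 0; qi < nQ; ++qi) {
    IntegerVector qv = queries[qi];
    std::vector<int> q(qv.begin(), qv.end());
    const int qlen = q.size();
    if (qlen < wordLen) continue;
    std::vector<std::pair<int, long long> > seeds;
    for (int p = 0; p + wordLen <= qlen; ++p)
      neighbors_dfs(q, p, wordLen, mat, neighborThresh, A, rowmax, seeds);

    for (int s = 0; s < nSub; ++s) {
      const std::vector<int> &S = sub[s];
      const int slen = S.size();
      if (slen < wordLen) continue;
      const long long epoch = (long long)qi * nSub + s;
      std::vector<Hit> cand;
      std::vector<std::pair<int, int> > gapped; // windows already aligned
      for (size_t k = 0; k < seeds.size(); ++k) {
        const int p = seeds[k].first;
        const long long w = seeds[k].second;
        const int from = idxStart[s][w], to = idxStart[s][w + 1];
        for (int t = from; t < to; ++t) {
          const int sp = idxPos[s][t];
          const int d = sp - p + qlen;   // shifted diagonal index
          if (covEpoch[d] == epoch && covVal[d] >= sp) continue;
          // ungapped x-drop extension around the word match
          int sc = 0;
          for (int u = 0; u < wordLen; ++u) sc += M[q[p + u] * A + S[sp + u]];
          int best = sc, qr = p + wordLen - 1, srr = sp + wordLen - 1;
          int i2 = p + wordLen, j2 = sp + wordLen, cur = sc;
          while (i2 < qlen && j2 < slen) {
            cur += M[q[i2] * A + S[j2]];
            if (cur > best) { best = cur; qr = i2; srr = j2; }
            if (best - cur > xDrop) break;
            ++i2; ++j2;
          }
          int sl = sp;
          i2 = p - 1; j2 = sp - 1; cur = best;
          int best2 = best;
          while (i2 >= 0 && j2 >= 0) {
            cur += M[q[i2] * A + S[j2]];
            if (cur > best2) { best2 = cur; sl = j2; }
            if (best2 - cur > xDrop) break;
            --i2; --j2;
          }
          covEpoch[d] = epoch; covVal[d] = srr;
          if (best2 < gapTrigger) continue;
          // gapped stage: full query vs a window around the ungapped segment
          int ws = sl - qlen - band; if (ws < 0) ws = 0;
          int we = srr + qlen + band; if (we > slen) we = slen;
          bool done = false;
          for (size_t g = 0; g < gapped.size(); ++g)
            if (ws >= gapped[g].first && we <= gapped[g].second) { done = true; break; }
          if (done) continue;
          gapped.push_back(std::make_pair(ws, we));
          std::vector<int> win(S.begin() + ws, S.begin() + we);
          Hit h; h.query = qi + 1; h.subject = s + 1;
          local_align_coords(q, win, mat, gapOpen, gapExt,
                             h.score, h.qs, h.qe, h.ss, h.se);
          if (h.score >= minReport && h.qs > 0) {
            h.ss += ws; h.se += ws;
            cand.push_back(h);
          }
        }
      }
      // dedupe: best score first (ties: lowest subject start), drop hits whose
      // subject span overlaps a kept hit
      std::sort(cand.begin(), cand.end(), [](const Hit &x, const Hit &y) {
        if (x.score != y.score) return x.score > y.score;
        return x.ss < y.ss;
      });
      std::vector<std::pair<int, int> > kept;
      for (size_t c = 0; c < cand.size(); ++c) {
        bool ov = false;
        for (size_t kk = 0; kk < kept.size(); ++kk)
          if (cand[c].ss <= kept[kk].second && cand[c].se >= kept[kk].first) {
            ov = true; break;
          }
        if (!ov) {
          kept.push_back(std::make_pair(cand[c].ss, cand[c].se));
          hits.push_back(cand[c]);
        }
      }
    }
  }

  const int n = hits.size();
  IntegerVector query(n), subject(n), score(n), qs(n), qe(n), ss(n), se(n);
  for (int i = 0; i < n; ++i) {
    query[i] = hits[i].query; subject[i] = hits[i].subject;
    score[i] = hits[i].score; qs[i] = hits[i].qs; qe[i] = hits[i].qe;
    ss[i] = hits[i].ss; se[i] = hits[i].se;
  }
  return DataFrame::create(_["query"] = query, _["subject"] = subject,
                           _["score"] = score, _["q_start"] = qs,
                           _["q_end"] = qe, _["s_start"] = ss,
                           _["s_end"] = se);
}
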