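#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Gotoh alignment with affine gaps (gap of length k costs open + k * ext)
// and free end gaps in both sequences ("overlap" / end-gap-free global).
// Sequences are 0-based integer codes into the substitution matrix.
// Scoring is integer (substitution-matrix units); the profile aligner at
// the bottom works on real-valued column scores instead.

static const int NEGI = -(1 << 28);
static const double NEGD = -1e30;

struct PairStats {
  int score;
  int matches;        // identical aligned residue pairs
  int aln_cols;       // aligned residue-pair columns (diagonal steps)
  int qs, qe, ts, te; // 1-based first/last aligned residue on each sequence
};

// Full-matrix Gotoh with traceback; buffers supplied by the caller so
// repeated calls do not reallocate.
static PairStats gotoh_full(const int* a, int m, const int* b, int n,
                            const int* sub, int ncode, int open, int ext,
                            std::vector<int>& Vb, std::vector<int>& Eb,
                            std::vector<int>& Fb) {
  const size_t W = (size_t)(n + 1);
  const size_t need = (size_t)(m + 1) * W;
  if (Vb.size() < need) { Vb.resize(need); Eb.resize(need); Fb.resize(need); }
  int* V = Vb.data(); int* E = Eb.data(); int* F = Fb.data();

  for (int j = 0; j <= n; ++j) { V[j] = 0; E[j] = NEGI; F[j] = NEGI; }
  for (int i = 1; i <= m; ++i) {
    size_t r = (size_t)i * W, p = r - W;
    V[r] = 0; E[r] = NEGI; F[r] = NEGI;
    const int* srow = sub + (size_t)a[i - 1] * ncode;
    for (int j = 1; j <= n; ++j) {
      int e = std::max(E[r + j - 1] - ext, V[r + j - 1] - open - ext);
      int f = std::max(F[p + j] - ext, V[p + j] - open - ext);
      int v = V[p + j - 1] + srow[b[j - 1]];
      if (e > v) v = e;
      if (f > v) v = f;
      E[r + j] = e; F[r + j] = f; V[r + j] = v;
    }
  }

  // Free trailing gaps: best cell on the last row or last column.
  int bi = m, bj = n;
  int best = V[(size_t)m * W + n];
  for (int j = n; j >= 0; --j) {
    int v = V[(size_t)m * W + j];
    if (v > best) { best = v; bi = m; bj = j; }
  }
  for (int i = m; i >= 0; --i) {
    int v = V[(size_t)i * W + n];
    if (v > best) { best = v; bi = i; bj = n; }
  }

  PairStats st; st.score = best; st.matches = 0; st.aln_cols = 0;
  st.qe = bi; st.te = bj;
  int i = bi, j = bj, state = 0; // 0=V, 1=E (gap in a), 2=F (gap in b)
  while (i > 0 && j > 0) {
    size_t r = (size_t)i * W, p = r - W;
    if (state == 0) {
      int v = V[r + j];
      int d = V[p + j - 1] + sub[(size_t)a[i - 1] * ncode + b[j - 1]];
      if (v == d) {
        st.aln_cols++;
        if (a[i - 1] == b[j - 1]) st.matches++;
        --i; --j;
      } else if (v == E[r + j]) state = 1;
      else state = 2;
    } else if (state == 1) {
      if (E[r + j] == E[r + j - 1] - ext) { --j; }
      else { --j; state = 0; }
    } else {
      if (F[r + j] == F[p + j] - ext) { --i; }
      else { --i; state = 0; }
    }
  }
  st.qs = i + 1; st.ts = j + 1;
  if (st.aln_cols == 0) { st.qs = st.qe = st.ts = st.te = 0; }
  return st;
}

// [[Rcpp::export]]
List cpp_gotoh_stats(IntegerVector a, IntegerVector b, IntegerMatrix sub,
                     int gap_open, int gap_ext) {
  std::vector<int> V, E, F;
  std::vector<int> av(a.begin(), a.end()), bv(b.begin(), b.end());
  PairStats st = gotoh_full(av.data(), av.size(), bv.data(), bv.size(),
                            INTEGER(sub), sub.ncol(), gap_open, gap_ext,
                            V, E, F);
  return List::create(_["score"] = st.score, _["matches"] = st.matches,
                      _["aln_cols"] = st.aln_cols,
                      _["q_start"] = st.qs, _["q_end"] = st.qe,
                      _["t_start"] = st.ts, _["t_end"] = st.te);
}

// Stats for an arbitrary list of index pairs (1-based into `seqs`).
// Returns one row per pair:
// score, matches, aln_cols, q_start, q_end, t_start, t_end.
// [[Rcpp::export]]
NumericMatrix cpp_pair_stats_many(List seqs, IntegerMatrix pairs,
                                  IntegerMatrix sub,
                                  int gap_open, int gap_ext) {
  int np = pairs.nrow();
  std::vector<std::vector<int> > S(seqs.size());
  for (int k = 0; k < seqs.size(); ++k) {
    IntegerVector v = seqs[k];
    S[k].assign(v.begin(), v.end());
  }
  NumericMatrix out(np, 7);
  std::vector<int> V, E, F;
  for (int p = 0; p < np; ++p) {
    const std::vector<int>& A = S[pairs(p, 0) - 1];
    const std::vector<int>& B = S[pairs(p, 1) - 1];
    PairStats st = gotoh_full(A.data(), A.size(), B.data(), B.size(),
                              INTEGER(sub), sub.ncol(), gap_open, gap_ext,
                              V, E, F);
    out(p, 0) = st.score; out(p, 1) = st.matches; out(p, 2) = st.aln_cols;
    out(p, 3) = st.qs; out(p, 4) = st.qe; out(p, 5) = st.ts; out(p, 6) = st.te;
    if ((p & 255) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Score-only overlap alignment of every A-sequence against every
// B-sequence (two rolling rows; used for best-hit score matrices).
// [[Rcpp::export]]
NumericMatrix cpp_score_matrix(List seqsA, List seqsB, IntegerMatrix sub,
                               int gap_open, int gap_ext) {
  int na = seqsA.size(), nb = seqsB.size(), ncode = sub.ncol();
  const int* SM = INTEGER(sub);
  std::vector<std::vector<int> > A(na), B(nb);
  for (int k = 0; k < na; ++k) { IntegerVector v = seqsA[k]; A[k].assign(v.begin(), v.end()); }
  for (int k = 0; k < nb; ++k) { IntegerVector v = seqsB[k]; B[k].assign(v.begin(), v.end()); }
  NumericMatrix out(na, nb);
  std::vector<int> V0v, V1v, F0v, F1v;
  for (int ia = 0; ia < na; ++ia) {
    const std::vector<int>& a = A[ia];
    int m = (int)a.size();
    for (int ib = 0; ib < nb; ++ib) {
      const std::vector<int>& b = B[ib];
      int n = (int)b.size();
      V0v.assign(n + 1, 0); F0v.assign(n + 1, NEGI);
      V1v.resize(n + 1); F1v.resize(n + 1);
      int* v0 = V0v.data(); int* v1 = V1v.data();
      int* f0 = F0v.data(); int* f1 = F1v.data();
      const int* bp = b.data();
      int best = 0; // empty overlap alignment is always available
      for (int i = 1; i <= m; ++i) {
        v1[0] = 0; f1[0] = NEGI;
        const int* srow = SM + (size_t)a[i - 1] * ncode;
        int eprev = NEGI;
        for (int j = 1; j <= n; ++j) {
          int ee = std::max(eprev - gap_ext, v1[j - 1] - gap_open - gap_ext);
          int ff = std::max(f0[j] - gap_ext, v0[j] - gap_open - gap_ext);
          int v = v0[j - 1] + srow[bp[j - 1]];
          if (ee > v) v = ee;
          if (ff > v) v = ff;
          f1[j] = ff; v1[j] = v;
          eprev = ee;
        }
        if (v1[n] > best) best = v1[n];
        std::swap(v0, v1); std::swap(f0, f1);
      }
      for (int j = 0; j <= n; ++j) if (v0[j] > best) best = v0[j];
      out(ia, ib) = best;
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// Global affine alignment over a precomputed column-score matrix S
// (rows = profile 1 columns, cols = profile 2 columns); end gaps are
// charged. Returns the move sequence from start to end: 1 = both
// profiles advance, 2 = profile-1 column only (gap in profile 2),
// 3 = profile-2 column only.
// [[Rcpp::export]]
IntegerVector cpp_affine_path(NumericMatrix S, double gap_open,
                              double gap_ext) {
  int m = S.nrow(), n = S.ncol();
  size_t W = (size_t)(n + 1);
  std::vector<double> V((size_t)(m + 1) * W), E((size_t)(m + 1) * W),
      F((size_t)(m + 1) * W);
  const double* Sp = REAL(S);
  V[0] = 0.0; E[0] = NEGD; F[0] = NEGD;
  for (int j = 1; j <= n; ++j) {
    E[j] = -gap_open - gap_ext * j; V[j] = E[j]; F[j] = NEGD;
  }
  for (int i = 1; i <= m; ++i) {
    size_t r = (size_t)i * W, p = r - W;
    F[r] = -gap_open - gap_ext * i; V[r] = F[r]; E[r] = NEGD;
    for (int j = 1; j <= n; ++j) {
      double e = std::max(E[r + j - 1] - gap_ext, V[r + j - 1] - gap_open - gap_ext);
      double f = std::max(F[p + j] - gap_ext, V[p + j] - gap_open - gap_ext);
      // S is column-major with m rows
      double v = V[p + j - 1] + Sp[(size_t)(j - 1) * m + (i - 1)];
      if (e > v) v = e;
      if (f > v) v = f;
      E[r + j] = e; F[r + j] = f; V[r + j] = v;
    }
  }
  std::vector<int> rev;
  int i = m, j = n, state = 0;
  while (i > 0 || j > 0) {
    size_t r = (size_t)i * W, p = (i > 0) ? r - W : 0;
    if (state == 0) {
      double v = V[r + j];
      if (i > 0 && j > 0 &&
          v == V[p + j - 1] + Sp[(size_t)(j - 1) * m + (i - 1)]) {
        rev.push_back(1); --i; --j; continue;
      }
      if (j > 0 && v == E[r + j]) { state = 1; continue; }
      if (i > 0 && v == F[r + j]) { state = 2; continue; }
      if (j > 0) { state = 1; continue; }
      state = 2; continue;
    } else if (state == 1) {
      rev.push_back(3);
      if (j > 1 && E[r + j] == E[r + j - 1] - gap_ext) { --j; }
      else { --j; state = 0; }
    } else {
      rev.push_back(2);
      if (i > 1 && F[r + j] == F[p + j] - gap_ext) { --i; }
      else { --i; state = 0; }
    }
  }
  IntegerVector out(rev.size());
  for (size_t k = 0; k < rev.size(); ++k) out[k] = rev[rev.size() - 1 - k];
  return out;
}
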