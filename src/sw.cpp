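#include <Rcpp.h>
#include <vector>
#include <climits>
using namespace Rcpp;

// Affine-gap Smith-Waterman. A gap of length k costs gap_open + k * gap_ext
// (the BLAST convention: BLOSUM62 with open 11 / extend 1 charges 12 for a
// one-residue gap). Sequences arrive as 0-based integer codes into the rows
// of the substitution matrix.

static const int NEG = INT_MIN / 4;

static inline int imax(int a, int b) { return a > b ? a : b; }

static int sw_score_core(const int* q, int m, const int* s, int n,
                         const IntegerMatrix& sub, int gap_open, int gap_ext) {
  std::vector<int> H(n + 1, 0), F(n + 1, NEG);
  int best = 0;
  for (int i = 1; i <= m; ++i) {
    int e = NEG;
    int diag = 0; // H[i-1][0]
    for (int j = 1; j <= n; ++j) {
      e = imax(e - gap_ext, H[j - 1] - gap_open - gap_ext);
      F[j] = imax(F[j] - gap_ext, H[j] - gap_open - gap_ext);
      int h = diag + sub(q[i - 1], s[j - 1]);
      h = imax(h, imax(e, F[j]));
      h = imax(h, 0);
      diag = H[j];
      H[j] = h;
      if (h > best) best = h;
    }
  }
  return best;
}

// [[Rcpp::export]]
int sw_score_one(IntegerVector q, IntegerVector s, IntegerMatrix sub,
                 int gap_open, int gap_ext) {
  return sw_score_core(INTEGER(q), q.size(), INTEGER(s), s.size(),
                       sub, gap_open, gap_ext);
}

// Best local score for every query x subject pair; rows = queries.
// [[Rcpp::export]]
IntegerMatrix sw_score_matrix(List queries, List subjects, IntegerMatrix sub,
                              int gap_open, int gap_ext) {
  const int nq = queries.size(), ns = subjects.size();
  IntegerMatrix out(nq, ns);
  std::vector<IntegerVector> qs(nq), ss(ns);
  for (int i = 0; i < nq; ++i) qs[i] = queries[i];
  for (int j = 0; j < ns; ++j) ss[j] = subjects[j];
  for (int i = 0; i < nq; ++i) {
    for (int j = 0; j < ns; ++j) {
      out(i, j) = sw_score_core(INTEGER(qs[i]), qs[i].size(),
                                INTEGER(ss[j]), ss[j].size(),
                                sub, gap_open, gap_ext);
    }
  }
  return out;
}

// Full dynamic-programming traceback for one pair. Deterministic: the
// alignment ends at the highest-scoring cell with the smallest (i, j) in
// row-major order, and the traceback prefers match > gap-in-subject >
// gap-in-query when states tie. Returns 1-based spans plus aligned residue
// index vectors (0 marks a gap).
// [[Rcpp::export]]
List sw_traceback(IntegerVector q, IntegerVector s, IntegerMatrix sub,
                  int gap_open, int gap_ext) {
  const int m = q.size(), n = s.size();
  const int W = n + 1;
  std::vector<int> H((m + 1) * W, 0), E((m + 1) * W, NEG), F((m + 1) * W, NEG);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      const int idx = i * W + j;
      E[idx] = imax(E[idx - 1] - gap_ext, H[idx - 1] - gap_open - gap_ext);
      F[idx] = imax(F[idx - W] - gap_ext, H[idx - W] - gap_open - gap_ext);
      int h = H[idx - W - 1] + sub(q[i - 1], s[j - 1]);
      h = imax(h, imax(E[idx], F[idx]));
      h = imax(h, 0);
      H[idx] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  std::vector<int> qa, sa; // reversed aligned indices, 0 = gap
  int i = bi, j = bj;
  int state = 0; // 0 = H, 1 = E (gap in query), 2 = F (gap in subject)
  while (i > 0 && j > 0) {
    const int idx = i * W + j;
    if (state == 0) {
      if (H[idx] == 0) break;
      if (H[idx] == H[idx - W - 1] + sub(q[i - 1], s[j - 1])) {
        qa.push_back(i); sa.push_back(j); --i; --j;
      } else if (H[idx] == F[idx]) {
        state = 2;
      } else {
        state = 1;
      }
    } else if (state == 2) { // gap in subject: consume query residue
      qa.push_back(i); sa.push_back(0);
      if (F[idx] == H[idx - W] - gap_open - gap_ext) state = 0;
      --i;
    } else { // gap in query: consume subject residue
      qa.push_back(0); sa.push_back(j);
      if (E[idx] == H[idx - 1] - gap_open - gap_ext) state = 0;
      --j;
    }
  }
  std::reverse(qa.begin(), qa.end());
  std::reverse(sa.begin(), sa.end());
  return List::create(_["score"] = best,
                      _["qstart"] = best > 0 ? i + 1 : NA_INTEGER,
                      _["qend"] = best > 0 ? bi : NA_INTEGER,
                      _["sstart"] = best > 0 ? j + 1 : NA_INTEGER,
                      _["send"] = best > 0 ? bj : NA_INTEGER,
                      _["qidx"] = IntegerVector(qa.begin(), qa.end()),
                      _["sidx"] = IntegerVector(sa.begin(), sa.end()));
}

// Longest common subsequence length of two integer sequences (synteny order
// score).
// [[Rcpp::export]]
int lcs_length_int(IntegerVector a, IntegerVector b) {
  const int m = a.size(), n = b.size();
  std::vector<int> prev(n + 1, 0), cur(n + 1, 0);
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      if (a[i - 1] == b[j - 1]) cur[j] = prev[j - 1] + 1;
      else cur[j] = imax(prev[j], cur[j - 1]);
    }
    std::swap(prev, cur);
  }
  return prev[n];
}
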