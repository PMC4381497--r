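// Affine-gap Smith-Waterman local alignment with traceback statistics.
// Scoring follows the BLASTN convention: a gap of length L costs
// gap_open + L * gap_extend. Characters are compared case-sensitively on
// the already upper-cased sequences; any non-identical pair (including
// IUPAC ambiguity codes) scores as a mismatch.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstring>
using namespace Rcpp;

namespace {

struct SwResult {
  int score, qstart, qend, sstart, send;
  int matches, mismatches, gap_openings, align_length;
};

const int NEG_INF = -1000000000;

SwResult sw_one(const std::string& q, const std::string& s,
                int match, int mismatch, int gap_open, int gap_ext,
                std::vector<int>& H, std::vector<int>& E, std::vector<int>& F,
                std::vector<unsigned char>& tbH,
                std::vector<unsigned char>& tbE,
                std::vector<unsigned char>& tbF) {
  const int m = (int)q.size(), n = (int)s.size();
  const int W = n + 1;
  const size_t need = (size_t)(m + 1) * W;
  if (H.size() < need) {
    H.resize(need); E.resize(need); F.resize(need);
    tbH.resize(need); tbE.resize(need); tbF.resize(need);
  }
  for (int j = 0; j <= n; ++j) { H[j] = 0; E[j] = NEG_INF; F[j] = NEG_INF; }
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    const size_t row = (size_t)i * W, prow = row - W;
    H[row] = 0; E[row] = NEG_INF; F[row] = NEG_INF;
    const char qc = q[i - 1];
    for (int j = 1; j <= n; ++j) {
      // E: gap in query (consumes subject char)
      int e_open = H[row + j - 1] - gap_open - gap_ext;
      int e_ext = E[row + j - 1] - gap_ext;
      int e = e_open >= e_ext ? e_open : e_ext;
      tbE[row + j] = e_open >= e_ext ? 0 : 1;
      // F: gap in subject (consumes query char)
      int f_open = H[prow + j] - gap_open - gap_ext;
      int f_ext = F[prow + j] - gap_ext;
      int f = f_open >= f_ext ? f_open : f_ext;
      tbF[row + j] = f_open >= f_ext ? 0 : 1;
      int diag = H[prow + j - 1] + (qc == s[j - 1] ? match : mismatch);
      int h = 0; unsigned char t = 0;
      if (diag >= h) { h = diag; t = 1; }
      if (e > h) { h = e; t = 2; }
      if (f > h) { h = f; t = 3; }
      if (h <= 0) { h = 0; t = 0; }
      H[row + j] = h; E[row + j] = e; F[row + j] = f; tbH[row + j] = t;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  SwResult r{best, 0, 0, 0, 0, 0, 0, 0, 0};
  if (best <= 0) return r;
  int i = bi, j = bj, state = 0;  // 0 = H, 1 = E, 2 = F
  while (true) {
    const size_t row = (size_t)i * W;
    if (state == 0) {
      unsigned char t = tbH[row + j];
      if (t == 0) break;
      if (t == 1) {
        ++r.align_length;
        if (q[i - 1] == s[j - 1]) ++r.matches; else ++r.mismatches;
        --i; --j;
      } else if (t == 2) state = 1;
      else state = 2;
    } else if (state == 1) {          // gap in query, consumes s[j-1]
      ++r.align_length;
      unsigned char t = tbE[row + j];
      --j;
      if (t == 0) { ++r.gap_openings; state = 0; }
    } else {                          // gap in subject, consumes q[i-1]
      ++r.align_length;
      unsigned char t = tbF[row + j];
      --i;
      if (t == 0) { ++r.gap_openings; state = 0; }
    }
  }
  r.qstart = i + 1; r.qend = bi; r.sstart = j + 1; r.send = bj;
  return r;
}

}  // namespace

// [[Rcpp::export(name = ".sw_align_batch")]]
IntegerMatrix sw_align_batch(CharacterVector queries, std::string subject,
                             int match, int mismatch,
                             int gap_open, int gap_ext) {
  const int nq = queries.size();
  IntegerMatrix out(nq, 9);
  colnames(out) = CharacterVector::create(
      "score", "qstart", "qend", "sstart", "send",
      "matches", "mismatches", "gap_openings", "align_length");
  std::vector<int> H, E, F;
  std::vector<unsigned char> tbH, tbE, tbF;
  for (int k = 0; k < nq; ++k) {
    std::string q = as<std::string>(queries[k]);
    SwResult r = sw_one(q, subject, match, mismatch, gap_open, gap_ext,
                        H, E, F, tbH, tbE, tbF);
    out(k, 0) = r.score; out(k, 1) = r.qstart; out(k, 2) = r.qend;
    out(k, 3) = r.sstart; out(k, 4) = r.send; out(k, 5) = r.matches;
    out(k, 6) = r.mismatches; out(k, 7) = r.gap_openings;
    out(k, 8) = r.align_length;
  }
  return out;
}
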