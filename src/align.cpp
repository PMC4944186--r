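#include <Rcpp.h>
#include <vector>
#include <string>
#include <climits>
using namespace Rcpp;

// Affine-gap pairwise alignment (Gotoh) with exact per-column operation
// counts. Cost model: +match for a match, -mismatch_cost for a mismatch,
// a gap of length k costs gap_open + k * gap_extend (LAST's a + b*k).
// State E: gap in the reference (insertion, consumes query base);
// state F: gap in the query (deletion, consumes reference base).
// Traceback ties resolve diagonal > deletion > insertion so repeated runs
// give identical column counts.
//
// The DP keeps one rolling row for H and E plus a register for F; the
// traceback variant additionally stores one byte per cell:
//   bits 0-1: H pointer (0 stop, 1 diagonal, 2 deletion, 3 insertion)
//   bit 2: E extends an existing gap; bit 3: F extends an existing gap.

static const int NEG = INT_MIN / 4;

static std::vector<signed char> encode(const std::string& s) {
  std::vector<signed char> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    switch (s[i]) {
      case 'A': v[i] = 0; break;
      case 'C': v[i] = 1; break;
      case 'G': v[i] = 2; break;
      case 'T': v[i] = 3; break;
      default:  v[i] = 4; // N: never matches, not even N vs N
    }
  }
  return v;
}

static int score_pass(const std::vector<signed char>& q,
                      const std::vector<signed char>& r,
                      int ma, int mm, int go, int ge, bool local) {
  const int n = (int)q.size(), m = (int)r.size();
  const int goe = go + ge;
  std::vector<int> H(m + 1), E(m + 1, NEG);
  for (int j = 0; j <= m; ++j) H[j] = local ? 0 : (j == 0 ? 0 : -(go + ge * j));
  int best = local ? 0 : NEG;
  for (int i = 1; i <= n; ++i) {
    int hdiag = H[0];
    H[0] = local ? 0 : -(go + ge * i);
    int f = NEG;
    const signed char qi = q[i - 1];
    for (int j = 1; j <= m; ++j) {
      const int hup = H[j];
      int e = hup - goe;
      const int eext = E[j] - ge;
      if (eext > e) e = eext;
      E[j] = e;
      int fo = H[j - 1] - goe;
      f -= ge;
      if (fo > f) f = fo;
      int h = hdiag + ((qi == r[j - 1] && qi < 4) ? ma : -mm);
      if (e > h) h = e;
      if (f > h) h = f;
      if (local && h < 0) h = 0;
      hdiag = hup;
      H[j] = h;
      if (local && h > best) best = h;
    }
  }
  return local ? best : H[m];
}

// [[Rcpp::export(name = ".align_score_cpp")]]
int align_score_cpp(std::string q, std::string r, int ma, int mm,
                    int go, int ge, bool local) {
  return score_pass(encode(q), encode(r), ma, mm, go, ge, local);
}

// [[Rcpp::export(name = ".align_scores_many_cpp")]]
IntegerVector align_scores_many_cpp(std::string q, CharacterVector refs,
                                    int ma, int mm, int go, int ge,
                                    bool local) {
  std::vector<signed char> qe = encode(q);
  IntegerVector out(refs.size());
  for (R_xlen_t k = 0; k < refs.size(); ++k) {
    out[k] = score_pass(qe, encode(as<std::string>(refs[k])), ma, mm, go, ge,
                        local);
  }
  return out;
}

// [[Rcpp::export(name = ".align_pair_cpp")]]
List align_pair_cpp(std::string qs, std::string rs, int ma, int mm,
                    int go, int ge, bool local) {
  const std::vector<signed char> q = encode(qs), r = encode(rs);
  const int n = (int)q.size(), m = (int)r.size();
  const int goe = go + ge;
  const size_t W = (size_t)m + 1;
  std::vector<unsigned char> tb((size_t)(n + 1) * W, 0);
  std::vector<int> H(m + 1), E(m + 1, NEG);
  for (int j = 0; j <= m; ++j) {
    H[j] = local ? 0 : (j == 0 ? 0 : -(go + ge * j));
    if (!local && j > 0) tb[j] = 2 | 8; // walk left along row 0, in-gap
  }
  int best = 0, bi = 0, bj = 0;
  if (!local) best = NEG;
  for (int i = 1; i <= n; ++i) {
    unsigned char* tbi = &tb[(size_t)i * W];
    int hdiag = H[0];
    H[0] = local ? 0 : -(go + ge * i);
    if (!local) tbi[0] = 3 | 4; // walk up along column 0, in-gap
    int f = NEG;
    const signed char qi = q[i - 1];
    for (int j = 1; j <= m; ++j) {
      const int hup = H[j];
      unsigned char flags = 0;
      const int eo = hup - goe, ee = E[j] - ge;
      int e;
      if (ee > eo) { e = ee; flags |= 4; } else e = eo;
      E[j] = e;
      const int fo = H[j - 1] - goe, fe = f - ge;
      if (fe > fo) { f = fe; flags |= 8; } else f = fo;
      int h = hdiag + ((qi == r[j - 1] && qi < 4) ? ma : -mm);
      unsigned char p = 1; // prefer diagonal, then deletion, then insertion
      if (f > h) { h = f; p = 2; }
      if (e > h) { h = e; p = 3; }
      if (local && h <= 0) { h = 0; p = 0; }
      tbi[j] = flags | p;
      hdiag = hup;
      H[j] = h;
      if (local && h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (!local) { best = H[m]; bi = n; bj = m; }

  std::string aq, ar;
  int i = bi, j = bj;
  int nmatch = 0, nmis = 0, nins = 0, ndel = 0;
  int state = 0; // 0 = in H, 2 = in F (deletion), 3 = in E (insertion)
  while (i > 0 || j > 0) {
    const unsigned char cell = tb[(size_t)i * W + (size_t)j];
    unsigned char p = state ? state : (unsigned char)(cell & 3);
    if (p == 0) break; // local alignment start
    if (p == 1) {
      aq.push_back(qs[i - 1]); ar.push_back(rs[j - 1]);
      if (q[i - 1] == r[j - 1] && q[i - 1] < 4) ++nmatch; else ++nmis;
      --i; --j; state = 0;
    } else if (p == 2) { // gap in query, consume reference
      aq.push_back('-'); ar.push_back(rs[j - 1]);
      ++ndel;
      state = (cell & 8) ? 2 : 0;
      --j;
    } else { // gap in reference, consume query
      aq.push_back(qs[i - 1]); ar.push_back('-');
      ++nins;
      state = (cell & 4) ? 3 : 0;
      --i;
    }
  }
  std::reverse(aq.begin(), aq.end());
  std::reverse(ar.begin(), ar.end());
  const int qstart = i + 1, rstart = j + 1; // 1-based span [start, bi/bj]

  return List::create(
      _["score"] = best, _["matches"] = nmatch, _["mismatches"] = nmis,
      _["insertions"] = nins, _["deletions"] = ndel,
      _["query_start"] = (bi >= qstart) ? qstart : NA_INTEGER,
      _["query_end"] = (bi >= qstart) ? bi : NA_INTEGER,
      _["ref_start"] = (bj >= rstart) ? rstart : NA_INTEGER,
      _["ref_end"] = (bj >= rstart) ? bj : NA_INTEGER,
      _["aligned_query"] = aq, _["aligned_ref"] = ar);
}
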