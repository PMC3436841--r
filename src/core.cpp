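// Core kernels: suffix array construction, BWT/FM-index queries with sampled
// occurrence checkpoints, sampled-suffix-array locate, the left-to-right LEM
// scan that yields MEM seeds, and affine-gap Smith-Waterman (score + traceback).
//
// Base encoding throughout: A=0, C=1, G=2, T=3, N=4. Index structures only
// ever see codes 0..3 (N positions carry a placeholder and are masked at the
// R level); reads may contain 4, which matches nothing.

#include <Rcpp.h>
#include <cstring>
#include <climits>
using namespace Rcpp;

static const int NEG_INF = INT_MIN / 4;

// ---------------------------------------------------------------------------
// encoding

// [[Rcpp::export]]
IntegerVector cpp_encode(std::string s) {
  int n = (int)s.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    switch (s[i]) {
      case 'A': case 'a': out[i] = 0; break;
      case 'C': case 'c': out[i] = 1; break;
      case 'G': case 'g': out[i] = 2; break;
      case 'T': case 't': out[i] = 3; break;
      case 'N': case 'n': out[i] = 4; break;
      default: out[i] = -1;
    }
  }
  return out;
}

// [[Rcpp::export]]
std::string cpp_revcomp(std::string s) {
  int n = (int)s.size();
  std::string out(n, 'N');
  for (int i = 0; i < n; ++i) {
    char c = s[n - 1 - i], r;
    switch (c) {
      case 'A': case 'a': r = 'T'; break;
      case 'C': case 'c': r = 'G'; break;
      case 'G': case 'g': r = 'C'; break;
      case 'T': case 't': r = 'A'; break;
      default: r = 'N';
    }
    out[i] = r;
  }
  return out;
}

// [[Rcpp::export]]
std::string cpp_decode(IntegerVector codes) {
  static const char* B = "ACGTN";
  std::string s(codes.size(), 'N');
  for (int i = 0; i < (int)codes.size(); ++i) {
    int c = codes[i];
    s[i] = (c >= 0 && c <= 4) ? B[c] : 'N';
  }
  return s;
}

// ---------------------------------------------------------------------------
// suffix array over text + terminal $ ($ encoded as rank 0, smaller than any
// base). Prefix-doubling with counting sorts: O(n log n).

// [[Rcpp::export]]
IntegerVector cpp_suffix_array(IntegerVector codes) {
  const int n = codes.size();
  const int m = n + 1;
  std::vector<int> sa(m), rnk(m), tmp(m), newr(m);
  for (int i = 0; i < m; ++i) { sa[i] = i; rnk[i] = (i < n) ? (codes[i] + 1) : 0; }

  // stable counting sort of sa by rnk[sa[i]]
  auto csort = [&](int K) {
    std::vector<int> c(K + 1, 0);
    for (int i = 0; i < m; ++i) c[rnk[sa[i]]]++;
    int sum = 0;
    for (int k = 0; k <= K; ++k) { int t = c[k]; c[k] = sum; sum += t; }
    for (int i = 0; i < m; ++i) tmp[c[rnk[sa[i]]]++] = sa[i];
    sa.swap(tmp);
  };

  csort(5);
  for (int len = 1; len < m; len <<= 1) {
    // order by second key (rank at i+len; absent sorts first)
    int p = 0;
    for (int i = m - len; i < m; ++i) tmp[p++] = i;
    for (int i = 0; i < m; ++i) if (sa[i] >= len) tmp[p++] = sa[i] - len;
    sa.swap(tmp);
    csort(m);
    // re-rank
    newr[sa[0]] = 0;
    for (int i = 1; i < m; ++i) {
      int a = sa[i], b = sa[i - 1];
      int a2 = (a + len < m) ? rnk[a + len] : -1;
      int b2 = (b + len < m) ? rnk[b + len] : -1;
      newr[a] = newr[b] + ((rnk[a] == rnk[b] && a2 == b2) ? 0 : 1);
    }
    rnk.swap(newr);
    if (rnk[sa[m - 1]] == m - 1) break;
  }
  return IntegerVector(sa.begin(), sa.end());
}

// ---------------------------------------------------------------------------
// BWT (2-bit packed, $ position kept separately)

static inline int bwt_at(const Rbyte* b, int i) {
  return (b[i >> 2] >> ((i & 3) << 1)) & 3;
}

// [[Rcpp::export]]
List cpp_bwt_build(IntegerVector codes, IntegerVector sa) {
  const int n = codes.size();
  const int m = n + 1;
  RawVector packed((m + 3) / 4);
  std::memset(RAW(packed), 0, packed.size());
  int dollar = -1;
  for (int i = 0; i < m; ++i) {
    int j = sa[i];
    int c = 0;
    if (j == 0) dollar = i; else c = codes[j - 1] & 3;
    packed[i >> 2] = (Rbyte)(packed[i >> 2] | (c << ((i & 3) << 1)));
  }
  return List::create(_["bwt"] = packed, _["dollar"] = dollar);
}

// [[Rcpp::export]]
RawVector cpp_pack_codes(IntegerVector codes) {
  const int m = codes.size();
  RawVector packed((m + 3) / 4);
  std::memset(RAW(packed), 0, packed.size());
  for (int i = 0; i < m; ++i)
    packed[i >> 2] = (Rbyte)(packed[i >> 2] | ((codes[i] & 3) << ((i & 3) << 1)));
  return packed;
}

// ---------------------------------------------------------------------------
// FM-index: occurrence checkpoints every u positions; C(.) excludes $.

// [[Rcpp::export]]
List cpp_fm_checkpoints(RawVector bwt, int dollar, int m, int u) {
  const int nck = m / u + 1;
  IntegerMatrix ck(4, nck);
  const Rbyte* b = RAW(bwt);
  long long cnt[4] = {0, 0, 0, 0};
  for (int i = 0; i <= m; ++i) {
    if (i % u == 0) {
      int j = i / u;
      if (j < nck) for (int a = 0; a < 4; ++a) ck(a, j) = (int)cnt[a];
    }
    if (i == m) break;
    if (i != dollar) cnt[bwt_at(b, i)]++;
  }
  IntegerVector counts(4);
  for (int a = 0; a < 4; ++a) counts[a] = (int)cnt[a];
  return List::create(_["checkpoints"] = ck, _["counts"] = counts);
}

struct FMView {
  const Rbyte* bwt; int dollar; const int* ck; int u; const int* C; int m;
  int occ(int a, int i) const {
    if (i < 0) return 0;
    int j = (i + 1) / u;
    int c = ck[4 * j + a];
    for (int k = j * u; k <= i; ++k) {
      if (k == dollar) continue;
      if (bwt_at(bwt, k) == a) ++c;
    }
    return c;
  }
  int lf(int i) const {
    if (i == dollar) return 0;
    int a = bwt_at(bwt, i);
    return C[a] + occ(a, i);
  }
  // backward-search update; interval is inclusive [lo, hi] over SA indices 0..m-1
  bool step(int a, int& lo, int& hi) const {
    int nlo = C[a] + occ(a, lo - 1) + 1;
    int nhi = C[a] + occ(a, hi);
    lo = nlo; hi = nhi;
    return lo <= hi;
  }
};

static FMView make_fm(RawVector& bwt, int dollar, IntegerMatrix& ck, int u,
                      IntegerVector& C, int n) {
  FMView f;
  f.bwt = RAW(bwt); f.dollar = dollar; f.ck = INTEGER(ck);
  f.u = u; f.C = INTEGER(C); f.m = n + 1;
  return f;
}

// [[Rcpp::export]]
int cpp_occ(RawVector bwt, int dollar, IntegerMatrix ck, int u, IntegerVector C,
            int n, int a, int i) {
  FMView f = make_fm(bwt, dollar, ck, u, C, n);
  return f.occ(a, i);
}

// [[Rcpp::export]]
int cpp_lf(RawVector bwt, int dollar, IntegerMatrix ck, int u, IntegerVector C,
           int n, int i) {
  FMView f = make_fm(bwt, dollar, ck, u, C, n);
  return f.lf(i);
}

// [[Rcpp::export]]
IntegerVector cpp_backward_search(RawVector bwt, int dollar, IntegerMatrix ck, int u,
                                  IntegerVector C, int n, IntegerVector pattern) {
  FMView f = make_fm(bwt, dollar, ck, u, C, n);
  int lo = 0, hi = n;
  for (int i = pattern.size() - 1; i >= 0; --i) {
    int a = pattern[i];
    if (a < 0 || a > 3) { lo = 1; hi = 0; break; }
    if (!f.step(a, lo, hi)) break;
  }
  return IntegerVector::create(lo, hi);
}

// ---------------------------------------------------------------------------
// sampled suffix array: retain text positions j with j % v == 0 (plus the $
// suffix), so any locate resolves in <= v LF steps.

struct SSAView {
  const Rbyte* marks; const int* rkb; const int* vals;
  bool marked(int i) const { return (marks[i >> 3] >> (i & 7)) & 1; }
  int rank(int i) const { // number of marked indices strictly before i
    int b = i >> 6;
    uint64_t w;
    std::memcpy(&w, marks + ((size_t)b << 3), 8);
    int r = (i & 63) ? __builtin_popcountll(w & (~0ULL >> (64 - (i & 63)))) : 0;
    return rkb[b] + r;
  }
};

static SSAView make_ssa(RawVector& marks, IntegerVector& rkb, IntegerVector& vals) {
  SSAView s;
  s.marks = RAW(marks); s.rkb = INTEGER(rkb); s.vals = INTEGER(vals);
  return s;
}

// [[Rcpp::export]]
List cpp_ssa_build(IntegerVector sa, int v) {
  const int m = sa.size();
  const int n = m - 1;
  const int nb = (m + 63) / 64;
  RawVector marks((R_xlen_t)nb * 8);
  std::memset(RAW(marks), 0, marks.size());
  std::vector<int> vals;
  for (int i = 0; i < m; ++i) {
    int t = sa[i];
    if (t % v == 0 || t == n) {
      marks[i >> 3] = (Rbyte)(marks[i >> 3] | (1 << (i & 7)));
      vals.push_back(t);
    }
  }
  IntegerVector rkb(nb);
  int c = 0;
  const Rbyte* mk = RAW(marks);
  for (int b = 0; b < nb; ++b) {
    rkb[b] = c;
    uint64_t w;
    std::memcpy(&w, mk + ((size_t)b << 3), 8);
    c += __builtin_popcountll(w);
  }
  return List::create(_["marks"] = marks, _["rankBlocks"] = rkb,
                      _["values"] = IntegerVector(vals.begin(), vals.end()));
}

static inline int locate_one(const FMView& f, const SSAView& s, int i) {
  int steps = 0;
  while (!s.marked(i)) { i = f.lf(i); ++steps; }
  return s.vals[s.rank(i)] + steps;
}

// [[Rcpp::export]]
IntegerVector cpp_locate(RawVector bwt, int dollar, IntegerMatrix ck, int u,
                         IntegerVector C, int n, RawVector marks,
                         IntegerVector rankBlocks, IntegerVector values,
                         int lo, int hi, int limit) {
  if (lo > hi) return IntegerVector(0);
  FMView f = make_fm(bwt, dollar, ck, u, C, n);
  SSAView s = make_ssa(marks, rankBlocks, values);
  int w = hi - lo + 1;
  int k = (limit < w) ? limit : w;
  IntegerVector out(k);
  for (int t = 0; t < k; ++t) out[t] = locate_one(f, s, lo + t);
  return out;
}

// ---------------------------------------------------------------------------
// left-to-right LEM scan (MEM seed generation). The index passed in is the
// one built over the REVERSED text, so that extending the read rightwards is
// a backward search; located positions are mapped back to forward coordinates.
// Containment rule: a LEM is recorded iff its end exceeds the end of the last
// recorded LEM and its length >= Q; up to h occurrences (smallest SA indices
// of the interval) are emitted per recorded LEM.

// [[Rcpp::export]]
IntegerMatrix cpp_mem_scan(IntegerVector read, RawVector bwt, int dollar,
                           IntegerMatrix ck, int u, IntegerVector C, int n,
                           RawVector marks, IntegerVector rankBlocks,
                           IntegerVector values, int Q, int h) {
  FMView f = make_fm(bwt, dollar, ck, u, C, n);
  SSAView s = make_ssa(marks, rankBlocks, values);
  const int L = read.size();
  std::vector<int> ro, gp, ln;
  int lastEnd = 0;
  for (int p = 0; p < L; ++p) {
    if (read[p] < 0 || read[p] > 3) continue;
    int lo = 0, hi = n, blo = -1, bhi = -1;
    int q = p;
    while (q < L && read[q] >= 0 && read[q] <= 3) {
      int tlo = lo, thi = hi;
      if (!f.step(read[q], tlo, thi)) break;
      lo = tlo; hi = thi; blo = lo; bhi = hi;
      ++q;
    }
    int len = q - p;
    if (len >= Q && q > lastEnd) {
      lastEnd = q;
      int w = bhi - blo + 1;
      int k = (h < w) ? h : w;
      for (int t = 0; t < k; ++t) {
        int revPos = locate_one(f, s, blo + t);
        ro.push_back(p);
        gp.push_back(n - revPos - len);
        ln.push_back(len);
      }
    }
  }
  IntegerMatrix out((int)ro.size(), 3);
  for (int i = 0; i < (int)ro.size(); ++i) {
    out(i, 0) = ro[i]; out(i, 1) = gp[i]; out(i, 2) = ln[i];
  }
  return out;
}

// ---------------------------------------------------------------------------
// affine-gap local alignment; a gap of length g costs gapOpen + g * gapExtend.
// N (code 4) never matches.

static inline int subst(int a, int b, int match, int mismatch) {
  return (a == b && a < 4) ? match : -mismatch;
}

// [[Rcpp::export]]
int cpp_sw_score(IntegerVector read, IntegerVector ref, int match, int mismatch,
                 int gapOpen, int gapExtend) {
  const int m = read.size(), n = ref.size();
  std::vector<int> Hp(n + 1, 0), Hc(n + 1, 0), Fv(n + 1, NEG_INF);
  int best = 0;
  for (int i = 1; i <= m; ++i) {
    int e = NEG_INF;
    Hc[0] = 0;
    const int a = read[i - 1];
    for (int j = 1; j <= n; ++j) {
      e = std::max(Hc[j - 1] - gapOpen - gapExtend, e - gapExtend);
      Fv[j] = std::max(Hp[j] - gapOpen - gapExtend, Fv[j] - gapExtend);
      int h = Hp[j - 1] + subst(a, ref[j - 1], match, mismatch);
      if (e > h) h = e;
      if (Fv[j] > h) h = Fv[j];
      if (h < 0) h = 0;
      Hc[j] = h;
      if (h > best) best = h;
    }
    Hp.swap(Hc);
  }
  return best;
}

// [[Rcpp::export]]
List cpp_sw_traceback(IntegerVector read, IntegerVector ref, int match,
                      int mismatch, int gapOpen, int gapExtend) {
  const int m = read.size(), n = ref.size();
  // flag bits per cell: 0-1 H source (0 stop, 1 diag, 2 E, 3 F);
  // bit 2: E extended from E; bit 3: F extended from F
  std::vector<uint8_t> fl((size_t)(m + 1) * (n + 1), 0);
  std::vector<int> Hp(n + 1, 0), Hc(n + 1, 0), Fv(n + 1, NEG_INF);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    int e = NEG_INF;
    Hc[0] = 0;
    const int a = read[i - 1];
    uint8_t* frow = &fl[(size_t)i * (n + 1)];
    for (int j = 1; j <= n; ++j) {
      int eOpen = Hc[j - 1] - gapOpen - gapExtend;
      int eExt = e - gapExtend;
      uint8_t bits = 0;
      if (eExt > eOpen) { e = eExt; bits |= 4; } else e = eOpen;
      int fOpen = Hp[j] - gapOpen - gapExtend;
      int fExt = Fv[j] - gapExtend;
      if (fExt > fOpen) { Fv[j] = fExt; bits |= 8; } else Fv[j] = fOpen;
      int h = Hp[j - 1] + subst(a, ref[j - 1], match, mismatch);
      uint8_t src = 1;
      if (e > h) { h = e; src = 2; }
      if (Fv[j] > h) { h = Fv[j]; src = 3; }
      if (h <= 0) { h = (h < 0) ? 0 : h; if (h == 0) src = 0; }
      Hc[j] = h;
      frow[j] = (uint8_t)(src | bits);
      if (h > best) { best = h; bi = i; bj = j; }
    }
    Hp.swap(Hc);
  }
  if (best <= 0) return List::create(_["score"] = 0);

  // walk back from (bi, bj)
  std::string ops;
  int i = bi, j = bj, state = 0;
  int nM = 0, nMis = 0, nI = 0, nD = 0;
  while (true) {
    uint8_t f = fl[(size_t)i * (n + 1) + j];
    if (state == 0) {
      int src = f & 3;
      if (src == 0) break;
      if (src == 1) {
        bool isM = (read[i - 1] == ref[j - 1] && read[i - 1] < 4);
        if (isM) ++nM; else ++nMis;
        ops.push_back('M');
        --i; --j;
      } else if (src == 2) state = 2;
      else state = 3;
    } else if (state == 2) { // gap in read: consumes reference -> D
      ops.push_back('D'); ++nD;
      if (!(f & 4)) state = 0;
      --j;
    } else {                 // gap in reference: consumes read -> I
      ops.push_back('I'); ++nI;
      if (!(f & 8)) state = 0;
      --i;
    }
  }
  // run-length encode reversed ops
  std::string cigar;
  int k = (int)ops.size();
  int t = k - 1;
  while (t >= 0) {
    char c = ops[t];
    int run = 0;
    while (t >= 0 && ops[t] == c) { ++run; --t; }
    cigar += std::to_string(run);
    cigar.push_back(c);
  }
  return List::create(_["score"] = best,
                      _["readStart"] = i, _["readEnd"] = bi,
                      _["refStart"] = j, _["refEnd"] = bj,
                      _["cigar"] = cigar,
                      _["nMatch"] = nM, _["nMismatch"] = nMis,
                      _["nIns"] = nI, _["nDel"] = nD);
}
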