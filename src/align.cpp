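#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <cstdint>
#include <climits>
using namespace Rcpp;

// Semi-global ("glocal") alignment: the read is aligned end to end, the
// reference contributes a local substring (free end gaps on the reference
// only).  Affine gaps: a gap of length k costs open + (k - 1) * extend,
// with positive costs supplied.  States: 0 = M (substitution column),
// 1 = X (gap in read, reference base consumed), 2 = Y (gap in reference,
// read base consumed).

static const int NEG = INT_MIN / 4;

// [[Rcpp::export]]
List cpp_align_semiglobal(std::string read, std::string ref,
                          int match, int mismatch,
                          int gap_open, int gap_extend) {
  const int m = (int) read.size();
  const int n = (int) ref.size();
  if (m < 1 || n < 1) stop("empty sequence");

  const int W = n + 1;
  std::vector<int> M((m + 1) * W, NEG), X((m + 1) * W, NEG), Y((m + 1) * W, NEG);
  // traceback pointers: previous state for each cell/state
  std::vector<uint8_t> pM((m + 1) * W, 0), pX((m + 1) * W, 0), pY((m + 1) * W, 0);

  for (int j = 0; j <= n; ++j) M[j] = 0;           // free reference prefix
  for (int i = 1; i <= m; ++i) {                   // read overhang left of ref
    Y[i * W] = -gap_open - (i - 1) * gap_extend;
    pY[i * W] = 2;
  }

  for (int i = 1; i <= m; ++i) {
    const char rb = read[i - 1];
    for (int j = 1; j <= n; ++j) {
      const int d = (i - 1) * W + (j - 1);
      const int u = (i - 1) * W + j;
      const int l = i * W + (j - 1);
      const int c = i * W + j;
      // M
      int best = M[d]; uint8_t ps = 0;
      if (X[d] > best) { best = X[d]; ps = 1; }
      if (Y[d] > best) { best = Y[d]; ps = 2; }
      if (best > NEG) {
        M[c] = best + ((rb == ref[j - 1]) ? match : mismatch);
        pM[c] = ps;
      }
      // X: gap in read, consume ref[j]
      best = NEG; ps = 0;
      if (M[l] > NEG && M[l] - gap_open > best) { best = M[l] - gap_open; ps = 0; }
      if (X[l] > NEG && X[l] - gap_extend > best) { best = X[l] - gap_extend; ps = 1; }
      if (Y[l] > NEG && Y[l] - gap_open > best) { best = Y[l] - gap_open; ps = 2; }
      if (best > NEG) { X[c] = best; pX[c] = ps; }
      // Y: gap in ref, consume read[i]
      best = NEG; ps = 0;
      if (M[u] > NEG && M[u] - gap_open > best) { best = M[u] - gap_open; ps = 0; }
      if (Y[u] > NEG && Y[u] - gap_extend > best) { best = Y[u] - gap_extend; ps = 1; }
      if (X[u] > NEG && X[u] - gap_open > best) { best = X[u] - gap_open; ps = 2; }
      if (best > NEG) { Y[c] = best; pY[c] = ps; }
    }
  }

  // best end: full read consumed, any reference suffix free; do not end in X
  // (a trailing gap-in-read is never optimal with positive gap costs)
  int bestScore = NEG, bestJ = 0; uint8_t bestState = 0;
  for (int j = 0; j <= n; ++j) {
    const int c = m * W + j;
    if (M[c] > bestScore) { bestScore = M[c]; bestJ = j; bestState = 0; }
    if (Y[c] > bestScore) { bestScore = Y[c]; bestJ = j; bestState = 2; }
  }

  // traceback
  std::string ra, qa;          // reference / read aligned strings (reversed)
  std::vector<int> pos5;       // read position per column, 0 for read gap
  int i = m, j = bestJ; uint8_t s = bestState;
  while (i > 0) {
    const int c = i * W + j;
    if (s == 0) {
      ra.push_back(ref[j - 1]); qa.push_back(read[i - 1]); pos5.push_back(i);
      s = pM[c]; --i; --j;
    } else if (s == 1) {
      ra.push_back(ref[j - 1]); qa.push_back('-'); pos5.push_back(0);
      s = pX[c]; --j;
    } else {
      ra.push_back('-'); qa.push_back(read[i - 1]); pos5.push_back(i);
      s = pY[c]; --i;
    }
  }
  const int refStart = j;      // 0-based start of consumed reference
  std::reverse(ra.begin(), ra.end());
  std::reverse(qa.begin(), qa.end());
  std::reverse(pos5.begin(), pos5.end());

  return List::create(_["score"] = bestScore,
                      _["ref_start"] = refStart,
                      _["ref_end"] = bestJ,
                      _["ref_aln"] = ra,
                      _["read_aln"] = qa,
                      _["pos5"] = IntegerVector(pos5.begin(), pos5.end()));
}

static inline int base2bits(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// TRUE when a and b share at least one exact k-mer (k <= 16)
// [[Rcpp::export]]
bool cpp_shared_kmer(std::string a, std::string b, int k) {
  if (k < 1 || k > 16) stop("k must be in 1..16");
  const int na = (int) a.size(), nb = (int) b.size();
  if (na < k || nb < k) return false;
  const uint32_t mask = (k == 16) ? 0xFFFFFFFFu : ((1u << (2 * k)) - 1);
  std::unordered_set<uint32_t> kmers;
  uint32_t h = 0; int run = 0;
  for (int i = 0; i < na; ++i) {
    int v = base2bits(a[i]);
    if (v < 0) { run = 0; h = 0; continue; }
    h = ((h << 2) | (uint32_t) v) & mask;
    if (++run >= k) kmers.insert(h);
  }
  h = 0; run = 0;
  for (int i = 0; i < nb; ++i) {
    int v = base2bits(b[i]);
    if (v < 0) { run = 0; h = 0; continue; }
    h = ((h << 2) | (uint32_t) v) & mask;
    if (++run >= k && kmers.count(h)) return true;
  }
  return false;
}

// Exact-seed anchored ungapped screen of query against subject (one strand).
// For every diagonal holding at least one exact k-mer match, the best
// ungapped segment (match +1 / mismatch -1, Kadane) is reported when its
// score reaches min_score.  Coordinates 1-based on the given strings.
// [[Rcpp::export]]
DataFrame cpp_screen_ungapped(std::string query, std::string subject,
                              int k, int min_score) {
  const int m = (int) query.size(), n = (int) subject.size();
  std::unordered_set<int> diags;
  if (m >= k && n >= k && k >= 1 && k <= 16) {
    const uint32_t mask = (k == 16) ? 0xFFFFFFFFu : ((1u << (2 * k)) - 1);
    std::unordered_multimap<uint32_t, int> smap;
    uint32_t h = 0; int run = 0;
    for (int j = 0; j < n; ++j) {
      int v = base2bits(subject[j]);
      if (v < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint32_t) v) & mask;
      if (++run >= k) smap.emplace(h, j - k + 1);
    }
    h = 0; run = 0;
    for (int i = 0; i < m; ++i) {
      int v = base2bits(query[i]);
      if (v < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint32_t) v) & mask;
      if (++run >= k) {
        auto rng = smap.equal_range(h);
        for (auto it = rng.first; it != rng.second; ++it)
          diags.insert(it->second - (i - k + 1));
      }
    }
  }
  std::vector<int> qs, ss, len, mat, sco;
  for (int d : diags) {
    const int i0 = std::max(0, -d);
    const int i1 = std::min(m, n - d);   // exclusive
    int cur = 0, curStart = i0;
    int best = 0, bestStart = i0, bestEnd = i0;   // [bestStart, bestEnd)
    for (int i = i0; i < i1; ++i) {
      const int s = (base2bits(query[i]) >= 0 &&
                     base2bits(query[i]) == base2bits(subject[i + d])) ? 1 : -1;
      if (cur <= 0) { cur = s; curStart = i; } else cur += s;
      if (cur > best) { best = cur; bestStart = curStart; bestEnd = i + 1; }
    }
    if (best >= min_score) {
      int nm = 0;
      for (int i = bestStart; i < bestEnd; ++i)
        if (base2bits(query[i]) >= 0 &&
            base2bits(query[i]) == base2bits(subject[i + d])) ++nm;
      qs.push_back(bestStart + 1);
      ss.push_back(bestStart + d + 1);
      len.push_back(bestEnd - bestStart);
      mat.push_back(nm);
      sco.push_back(best);
    }
  }
  return DataFrame::create(_["q_start"] = qs, _["s_start"] = ss,
                           _["length"] = len, _["matches"] = mat,
                           _["score"] = sco);
}
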