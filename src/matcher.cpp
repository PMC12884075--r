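// Edit-bounded short-query matching.
//
// Contract shared by both scan routes: for each (query, contig, strand,
// 0-based start offset) report at most one full-span alignment -- the best
// admissible one under (<= max_mm substitutions, <= max_gap gap columns),
// ranked by fewer gap columns, then fewer mismatches, then span preference
// L, L-1, L+1.  End gaps count as gap columns (they appear as a gap
// placement at the first/last position of a gapped shape).
//
// cpp_scan_hits       : seed-and-extend (pigeonhole seeds, banded verify)
// cpp_scan_hits_brute : literal per-offset scan, kept independent as oracle

#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <set>
#include <string>
#include <vector>

using namespace Rcpp;

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    default:  return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = comp_base(r[i]);
  return r;
}

// [[Rcpp::export(name = "cpp_revcomp")]]
CharacterVector cpp_revcomp(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i)
    out[i] = revcomp(as<std::string>(x[i]));
  out.names() = x.names();
  return out;
}

struct RawAln {
  int start;  // 0-based on forward contig
  int span;   // genome bases covered: L-1, L, or L+1
  int gap;    // gap columns (0 or 1)
  int mm;     // substitutions
};

// ---- shared low-level pieces (each route calls its own copy of the logic
// ---- for the search; the per-shape arithmetic below is the contract) -----

static inline int hamming(const char* p, const char* t, int L, int cap) {
  int mm = 0;
  for (int i = 0; i < L; ++i) {
    if (p[i] != t[i] && ++mm > cap) return mm;
  }
  return mm;
}

// Best mismatch count for one gapped shape via prefix/suffix split.
// del_in_query = true : genome span L-1, one query base opposite a gap.
// del_in_query = false: genome span L+1, one genome base opposite a gap.
static int best_gapped_mm(const char* p, const char* t, int L,
                          bool del_in_query) {
  // pre[i]: mismatches of p[0..i-1] vs t[0..i-1]
  // suf[i]: mismatches of p[i..L-1] vs t[i +- 1 ..], shifted by the gap
  std::vector<int> pre(L + 1, 0), suf(L + 1, 0);
  int lim = del_in_query ? (L - 1) : L;  // aligned prefix columns available
  for (int i = 0; i < lim; ++i) pre[i + 1] = pre[i] + (p[i] != t[i] ? 1 : 0);
  if (del_in_query) {
    // after gapping query base g: p[g+1..L-1] vs t[g..L-2]
    for (int i = L - 1; i >= 1; --i)
      suf[i] = suf[i + 1] + (p[i] != t[i - 1] ? 1 : 0);
    int best = INT_MAX;
    for (int g = 0; g < L; ++g) {
      int mm = pre[g] + suf[g + 1];
      if (mm < best) best = mm;
    }
    return best;
  } else {
    // after gapping genome base g (0..L): p[g..L-1] vs t[g+1..L]
    for (int i = L - 1; i >= 0; --i)
      suf[i] = suf[i + 1] + (p[i] != t[i + 1] ? 1 : 0);
    int best = INT_MAX;
    for (int g = 0; g <= L; ++g) {
      int mm = (g > 0 ? pre[g] : 0) + suf[g];
      if (mm < best) best = mm;
    }
    return best;
  }
}

// Evaluate the canonical best alignment at one offset.  Returns true and
// fills `out` when an admissible alignment exists.
static bool eval_offset(const std::string& P, const std::string& T,
                        int start, int max_mm, int max_gap, RawAln& out) {
  const int L = (int)P.size();
  const int N = (int)T.size();
  if (start < 0) return false;
  bool found = false;
  RawAln best;
  // shape L (preferred)
  if (start + L <= N) {
    int mm = hamming(P.c_str(), T.c_str() + start, L, max_mm);
    if (mm <= max_mm) {
      best = {start, L, 0, mm};
      found = true;
    }
  }
  if (max_gap >= 1 && L >= 2) {
    // shape L-1, then L+1; only beat a found shape on (gap, mm) order
    if (start + L - 1 <= N) {
      int mm = best_gapped_mm(P.c_str(), T.c_str() + start, L, true);
      if (mm <= max_mm) {
        RawAln cand = {start, L - 1, 1, mm};
        if (!found || cand.gap < best.gap ||
            (cand.gap == best.gap && cand.mm < best.mm)) {
          best = cand; found = true;
        }
      }
    }
    if (start + L + 1 <= N) {
      int mm = best_gapped_mm(P.c_str(), T.c_str() + start, L, false);
      if (mm <= max_mm) {
        RawAln cand = {start, L + 1, 1, mm};
        if (!found || cand.gap < best.gap ||
            (cand.gap == best.gap && cand.mm < best.mm)) {
          best = cand; found = true;
        }
      }
    }
  }
  if (found) out = best;
  return found;
}

// ---- route 1: seed-and-extend -------------------------------------------

static void scan_one_strand_seeded(const std::string& P, const std::string& T,
                                   int max_mm, int max_gap,
                                   std::vector<RawAln>& out) {
  const int L = (int)P.size();
  const int N = (int)T.size();
  if (N < L - (max_gap >= 1 ? 1 : 0)) return;
  const int e = max_mm + max_gap;
  const int nseed = e + 1;
  const int seed_len = L / nseed;
  std::set<int> starts;
  if (seed_len < 4) {
    // query too short to seed profitably: evaluate every offset
    for (int i = 0; i <= N - (L - 1); ++i) starts.insert(i);
  } else {
    for (int si = 0; si < nseed; ++si) {
      const int q0 = si * seed_len;
      const char* seed = P.c_str() + q0;
      for (int t = 0; t + seed_len <= N; ++t) {
        if (std::memcmp(seed, T.c_str() + t, seed_len) == 0) {
          for (int d = -max_gap; d <= max_gap; ++d) {
            int c = t - q0 + d;
            if (c >= 0 && c <= N - (L - 1)) starts.insert(c);
          }
        }
      }
    }
  }
  RawAln a;
  for (int c : starts)
    if (eval_offset(P, T, c, max_mm, max_gap, a)) out.push_back(a);
}

// ---- route 2: brute force, every offset ---------------------------------
// Independent evaluation: literal mismatch counting per gap placement with
// an early cap, no prefix/suffix arrays, no seeding.

static bool eval_offset_brute(const std::string& P, const std::string& T,
                              int start, int max_mm, int max_gap,
                              RawAln& out) {
  const int L = (int)P.size();
  const int N = (int)T.size();
  if (start < 0) return false;
  bool found = false;
  RawAln best;
  if (start + L <= N) {
    int mm = 0;
    for (int i = 0; i < L && mm <= max_mm; ++i)
      if (P[i] != T[start + i]) ++mm;
    if (mm <= max_mm) { best = {start, L, 0, mm}; found = true; }
  }
  if (max_gap >= 1 && L >= 2) {
    if (start + L - 1 <= N) {  // one query base opposite a gap
      int bestmm = INT_MAX;
      for (int g = 0; g < L; ++g) {
        int mm = 0;
        for (int i = 0; i < L && mm <= max_mm; ++i) {
          if (i == g) continue;
          int ti = start + (i < g ? i : i - 1);
          if (P[i] != T[ti]) ++mm;
        }
        if (mm < bestmm) bestmm = mm;
      }
      if (bestmm <= max_mm && !found) {
        best = {start, L - 1, 1, bestmm};
        found = true;  // a gapless alignment always outranks a gapped one
      }
    }
    if (start + L + 1 <= N) {  // one genome base opposite a gap
      int bestmm = INT_MAX;
      for (int g = 0; g <= L; ++g) {
        int mm = 0;
        for (int i = 0; i < L && mm <= max_mm; ++i) {
          int ti = start + (i < g ? i : i + 1);
          if (P[i] != T[ti]) ++mm;
        }
        if (mm < bestmm) bestmm = mm;
      }
      if (bestmm <= max_mm) {
        RawAln cand = {start, L + 1, 1, bestmm};
        // preferred over the L-1 gapped shape only on strictly fewer mm;
        // never preferred over a gapless alignment
        if (!found || (best.gap == 1 && cand.mm < best.mm)) {
          best = cand; found = true;
        }
      }
    }
  }
  if (found) out = best;
  return found;
}

static void scan_one_strand_brute(const std::string& P, const std::string& T,
                                  int max_mm, int max_gap,
                                  std::vector<RawAln>& out) {
  const int L = (int)P.size();
  const int N = (int)T.size();
  RawAln a;
  for (int c = 0; c <= N - (L - 1); ++c)
    if (eval_offset_brute(P, T, c, max_mm, max_gap, a)) out.push_back(a);
}

static DataFrame collect_hits(const std::string& query,
                              CharacterVector contigs, int max_mm,
                              int max_gap, bool brute) {
  CharacterVector cnames = contigs.names();
  std::vector<std::string> o_contig, o_strand;
  std::vector<int> o_start, o_end, o_gap, o_mm, o_span;
  const std::string qrc = revcomp(query);
  for (R_xlen_t ci = 0; ci < contigs.size(); ++ci) {
    const std::string T = as<std::string>(contigs[ci]);
    const std::string cname = as<std::string>(cnames[ci]);
    for (int sidx = 0; sidx < 2; ++sidx) {
      const std::string& P = (sidx == 0) ? query : qrc;
      std::vector<RawAln> raw;
      if (brute)
        scan_one_strand_brute(P, T, max_mm, max_gap, raw);
      else
        scan_one_strand_seeded(P, T, max_mm, max_gap, raw);
      for (const RawAln& a : raw) {
        o_contig.push_back(cname);
        o_strand.push_back(sidx == 0 ? "+" : "-");
        o_start.push_back(a.start + 1);
        o_end.push_back(a.start + a.span);
        o_gap.push_back(a.gap);
        o_mm.push_back(a.mm);
        o_span.push_back(a.span);
      }
    }
  }
  return DataFrame::create(
      _["contig"] = o_contig, _["start"] = o_start, _["end"] = o_end,
      _["strand"] = o_strand, _["gap_columns"] = o_gap,
      _["mismatches"] = o_mm, _["span"] = o_span,
      _["stringsAsFactors"] = false);
}

// [[Rcpp::export(name = "cpp_scan_hits")]]
DataFrame cpp_scan_hits(std::string query, CharacterVector contigs,
                        int max_mm, int max_gap) {
  return collect_hits(query, contigs, max_mm, max_gap, false);
}

// [[Rcpp::export(name = "cpp_scan_hits_brute")]]
DataFrame cpp_scan_hits_brute(std::string query, CharacterVector contigs,
                              int max_mm, int max_gap) {
  return collect_hits(query, contigs, max_mm, max_gap, true);
}

// ---- MinHash sketching ---------------------------------------------------

// MurmurHash3 x64-128 (public-domain reference algorithm); low 64 bits used.
static inline uint64_t rotl64(uint64_t x, int8_t r) {
  return (x << r) | (x >> (64 - r));
}
static inline uint64_t fmix64(uint64_t k) {
  k ^= k >> 33; k *= 0xff51afd7ed558ccdULL;
  k ^= k >> 33; k *= 0xc4ceb9fe1a85ec53ULL;
  k ^= k >> 33;
  return k;
}

static uint64_t murmur3_64(const char* key, int len, uint32_t seed) {
  const uint8_t* data = (const uint8_t*)key;
  const int nblocks = len / 16;
  uint64_t h1 = seed, h2 = seed;
  const uint64_t c1 = 0x87c37b91114253d5ULL, c2 = 0x4cf5ad432745937fULL;
  const uint64_t* blocks = (const uint64_t*)(data);
  for (int i = 0; i < nblocks; i++) {
    uint64_t k1, k2;
    std::memcpy(&k1, blocks + i * 2, 8);
    std::memcpy(&k2, blocks + i * 2 + 1, 8);
    k1 *= c1; k1 = rotl64(k1, 31); k1 *= c2; h1 ^= k1;
    h1 = rotl64(h1, 27); h1 += h2; h1 = h1 * 5 + 0x52dce729;
    k2 *= c2; k2 = rotl64(k2, 33); k2 *= c1; h2 ^= k2;
    h2 = rotl64(h2, 31); h2 += h1; h2 = h2 * 5 + 0x38495ab5;
  }
  const uint8_t* tail = (const uint8_t*)(data + nblocks * 16);
  uint64_t k1 = 0, k2 = 0;
  switch (len & 15) {
    case 15: k2 ^= ((uint64_t)tail[14]) << 48;
    case 14: k2 ^= ((uint64_t)tail[13]) << 40;
    case 13: k2 ^= ((uint64_t)tail[12]) << 32;
    case 12: k2 ^= ((uint64_t)tail[11]) << 24;
    case 11: k2 ^= ((uint64_t)tail[10]) << 16;
    case 10: k2 ^= ((uint64_t)tail[9]) << 8;
    case  9: k2 ^= ((uint64_t)tail[8]) << 0;
             k2 *= c2; k2 = rotl64(k2, 33); k2 *= c1; h2 ^= k2;
    case  8: k1 ^= ((uint64_t)tail[7]) << 56;
    case  7: k1 ^= ((uint64_t)tail[6]) << 48;
    case  6: k1 ^= ((uint64_t)tail[5]) << 40;
    case  5: k1 ^= ((uint64_t)tail[4]) << 32;
    case  4: k1 ^= ((uint64_t)tail[3]) << 24;
    case  3: k1 ^= ((uint64_t)tail[2]) << 16;
    case  2: k1 ^= ((uint64_t)tail[1]) << 8;
    case  1: k1 ^= ((uint64_t)tail[0]) << 0;
             k1 *= c1; k1 = rotl64(k1, 31); k1 *= c2; h1 ^= k1;
  }
  h1 ^= len; h2 ^= len;
  h1 += h2; h2 += h1;
  h1 = fmix64(h1); h2 = fmix64(h2);
  h1 += h2;
  return h1;
}

static inline bool acgt_ok(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

// Bottom-s MinHash over canonical k-mers (lexicographic min of the k-mer
// and its reverse complement).  Returns hashes as fixed-width hex strings
// sorted ascending, plus the count of distinct canonical k-mers seen.
// [[Rcpp::export(name = "cpp_sketch_kmers")]]
List cpp_sketch_kmers(CharacterVector seqs, int k, int s, int seed) {
  std::set<uint64_t> all;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string seq = as<std::string>(seqs[i]);
    for (auto& c : seq) c = toupper(c);
    const int N = (int)seq.size();
    if (N < k) continue;
    std::string kmer(k, 'N'), rc(k, 'N');
    for (int p = 0; p + k <= N; ++p) {
      bool ok = true;
      for (int j = 0; j < k; ++j) {
        char c = seq[p + j];
        if (!acgt_ok(c)) { ok = false; break; }
        kmer[j] = c;
        rc[k - 1 - j] = comp_base(c);
      }
      if (!ok) continue;
      const std::string& canon = (kmer <= rc) ? kmer : rc;
      uint64_t h = murmur3_64(canon.c_str(), k, (uint32_t)seed);
      all.insert(h);
    }
  }
  const size_t n_kmers = all.size();
  std::vector<uint64_t> v(all.begin(), all.end());
  if ((int)v.size() > s) v.resize(s);
  CharacterVector out(v.size());
  char buf[17];
  for (size_t i = 0; i < v.size(); ++i) {
    std::snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)v[i]);
    out[i] = buf;
  }
  return List::create(_["hashes"] = out,
                      _["n_distinct_kmers"] = (double)n_kmers);
}
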