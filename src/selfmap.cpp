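#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
#include <cctype>
using namespace Rcpp;

// Base encoding: A=0 C=1 G=2 T=3, anything else (N) = 4.
// N never matches anything, including another N: a site that cannot be
// read cannot confirm a match.
static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;
  }
}

static inline int comp_code(int c) { return c < 4 ? 3 - c : 4; }

static inline int hamming(const int8_t* a, const int8_t* b, int L, int cap) {
  int d = 0;
  for (int k = 0; k < L; ++k) {
    if (a[k] != b[k] || a[k] >= 4) {
      if (++d > cap) return d;
    }
  }
  return d;
}

// Pack a half-window of codes into a 64-bit key; returns false if the
// half contains an unreadable base (cannot participate in exact matching).
static inline bool pack_half(const int8_t* w, int from, int len, uint64_t& key) {
  uint64_t k = 0;
  for (int i = 0; i < len; ++i) {
    int8_t c = w[from + i];
    if (c >= 4) return false;
    k = (k << 2) | (uint64_t)c;
  }
  key = k;
  return true;
}

// Self-mapping coverage of a genome with read length L and up to max_mm
// mismatches (0 or 1), both strands, reads allowed to map to multiple
// placements. Returns per-position count of (read, placement) pairs
// spanning the position.
//
// Every length-L window of the forward strand and its reverse complement
// is a read; every offset on either strand is a placement. By strand
// symmetry of the Hamming distance under reverse complement, the number
// of read-placements at offset j equals
//   2 * ( #{i : H(w_i, w_j) <= mm} + #{i : H(w_i, rc(w_j)) <= mm} ).
// Candidate i's are found by pigeonhole seeding: within Hamming <= 1 at
// least one of the two half-windows matches exactly.
// [[Rcpp::export]]
IntegerVector selfmap_coverage_cpp(std::string genome, int L, int max_mm,
                                   bool circular) {
  const int n = (int)genome.size();
  IntegerVector cov(n, 0);
  int n_off = circular ? n : n - L + 1;
  if (n_off <= 0 || n == 0) return cov;

  std::vector<int8_t> g(n);
  for (int i = 0; i < n; ++i) g[i] = (int8_t)base_code(genome[i]);

  // forward windows and their reverse complements, flattened
  std::vector<int8_t> W((size_t)n_off * L), R((size_t)n_off * L);
  for (int j = 0; j < n_off; ++j) {
    for (int k = 0; k < L; ++k) {
      int8_t c = g[(j + k) % n];
      W[(size_t)j * L + k] = c;
      R[(size_t)j * L + (L - 1 - k)] = (int8_t)comp_code(c);
    }
  }

  const int h1 = L / 2, h2 = L - h1;
  std::unordered_map<uint64_t, std::vector<int>> idx1, idx2;
  idx1.reserve((size_t)n_off * 2);
  idx2.reserve((size_t)n_off * 2);
  for (int j = 0; j < n_off; ++j) {
    uint64_t key;
    if (pack_half(&W[(size_t)j * L], 0, h1, key)) idx1[key].push_back(j);
    if (pack_half(&W[(size_t)j * L], h1, h2, key)) idx2[key].push_back(j);
  }

  std::vector<int> stamp(n_off, -1);
  int stamp_id = 0;
  std::vector<int> cand;
  cand.reserve(64);

  // count forward-window reads within max_mm of query q
  auto count_matches = [&](const int8_t* q) -> int {
    ++stamp_id;
    cand.clear();
    uint64_t key;
    if (pack_half(q, 0, h1, key)) {
      auto it = idx1.find(key);
      if (it != idx1.end())
        for (int i : it->second)
          if (stamp[i] != stamp_id) { stamp[i] = stamp_id; cand.push_back(i); }
    }
    if (max_mm >= 1 && pack_half(q, h1, h2, key)) {
      auto it = idx2.find(key);
      if (it != idx2.end())
        for (int i : it->second)
          if (stamp[i] != stamp_id) { stamp[i] = stamp_id; cand.push_back(i); }
    }
    int m = 0;
    for (int i : cand)
      if (hamming(&W[(size_t)i * L], q, L, max_mm) <= max_mm) ++m;
    return m;
  };

  for (int j = 0; j < n_off; ++j) {
    int c1 = count_matches(&W[(size_t)j * L]);
    int c2 = count_matches(&R[(size_t)j * L]);
    int placements = 2 * (c1 + c2);
    if (placements == 0) continue;
    for (int k = 0; k < L; ++k) cov[(j + k) % n] += placements;
  }
  return cov;
}

// Decode classic samtools pileup read-base strings into ACGT counts.
// "." and "," count as the reference base; "^X" (read start + mapping
// quality char) and "$" are stripped; "+n<seq>"/"-n<seq>" indels and "*"
// deletion placeholders and N are skipped. Case-insensitive.
// [[Rcpp::export]]
IntegerMatrix decode_pileup_cpp(CharacterVector bases, CharacterVector refs) {
  const int n = bases.size();
  if (refs.size() != n) stop("read strings and reference bases differ in length");
  IntegerMatrix out(n, 4);
  colnames(out) = CharacterVector::create("A", "C", "G", "T");
  for (int r = 0; r < n; ++r) {
    std::string s = as<std::string>(bases[r]);
    std::string rf = as<std::string>(refs[r]);
    int ref_code = rf.empty() ? 4 : base_code(rf[0]);
    size_t i = 0, len = s.size();
    while (i < len) {
      char c = s[i];
      if (c == '^') {
        if (i + 1 >= len)
          stop("truncated read-start marker in pileup read string at row %d", r + 1);
        i += 2;
      } else if (c == '$') {
        ++i;
      } else if (c == '+' || c == '-') {
        ++i;
        size_t d0 = i;
        long ilen = 0;
        while (i < len && isdigit((unsigned char)s[i])) {
          ilen = ilen * 10 + (s[i] - '0');
          ++i;
        }
        if (i == d0)
          stop("truncated indel length field in pileup read string at row %d", r + 1);
        if (i + (size_t)ilen > len)
          stop("truncated indel sequence in pileup read string at row %d", r + 1);
        i += (size_t)ilen;
      } else if (c == '.' || c == ',') {
        if (ref_code < 4) ++out(r, ref_code);
        ++i;
      } else {
        int code = base_code(c);
        if (code < 4) ++out(r, code);
        ++i; // N, n, *, <, > skipped
      }
    }
  }
  return out;
}
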