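// Canonical k-mer engine: 2-bit rolling encoding of A/C/G/T windows, strand
// collapsed to the lexicographic minimum of a k-mer and its reverse
// complement.  Lexicographic order on ACGT strings coincides with numeric
// order of the 2-bit codes, so sorting and min() operate on codes directly.
// k is limited to 31 so a k-mer fits one uint64.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <string>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

static inline int base2bits(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static const char BITS2BASE[4] = {'A', 'C', 'G', 'T'};

static std::string decode_kmer(uint64_t code, int k) {
  std::string s((size_t)k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[(size_t)i] = BITS2BASE[code & 3ULL];
    code >>= 2;
  }
  return s;
}

static void check_k(int k) {
  if (k < 1 || k > 31)
    stop("k must be between 1 and 31 (got %d)", k);
}

// Scan one sequence, calling f(canonical_code) for every window made of
// A/C/G/T only (case-insensitive); any other character voids the windows
// covering it.
template <typename F>
static void scan_canonical(const char *seq, size_t n, int k, F &&f) {
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  const int shift = 2 * (k - 1);
  uint64_t fwd = 0, rev = 0;
  int run = 0;
  for (size_t i = 0; i < n; ++i) {
    int b = base2bits(seq[i]);
    if (b < 0) {
      run = 0;
      fwd = rev = 0;
      continue;
    }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - b) << shift);
    if (++run >= k)
      f(fwd < rev ? fwd : rev);
  }
}

// Encode a full-length k-mer; returns false on any non-ACGT character.
static bool encode_kmer(const char *s, int k, uint64_t &fwd, uint64_t &rev) {
  const int shift = 2 * (k - 1);
  fwd = rev = 0;
  for (int i = 0; i < k; ++i) {
    int b = base2bits(s[i]);
    if (b < 0)
      return false;
    fwd = (fwd << 2) | (uint64_t)b;
    rev = (rev >> 2) | ((uint64_t)(3 - b) << shift);
  }
  return true;
}

// [[Rcpp::export]]
List cpp_count_kmers(CharacterVector seqs, int k) {
  check_k(k);
  std::unordered_map<uint64_t, double> counts;
  double n_windows = 0;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    if (STRING_ELT(seqs, i) == NA_STRING)
      continue;
    const char *s = CHAR(seqs[i]);
    size_t n = (size_t)LENGTH(seqs[i]);
    scan_canonical(s, n, k, [&](uint64_t code) {
      ++counts[code];
      ++n_windows;
    });
  }
  std::vector<uint64_t> keys;
  keys.reserve(counts.size());
  for (auto &kv : counts)
    keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  R_xlen_t m = (R_xlen_t)keys.size();
  CharacterVector kmer(m);
  NumericVector count(m);
  for (R_xlen_t i = 0; i < m; ++i) {
    kmer[i] = decode_kmer(keys[(size_t)i], k);
    count[i] = counts[keys[(size_t)i]];
  }
  return List::create(_["kmer"] = kmer, _["count"] = count,
                      _["n_windows"] = n_windows);
}

// Build code -> index map for a set of k-mers (canonicalized on entry).
// Duplicate canonical codes keep the first index.
static std::unordered_map<uint64_t, R_xlen_t>
key_index(const CharacterVector &keys, int k) {
  std::unordered_map<uint64_t, R_xlen_t> idx;
  idx.reserve((size_t)keys.size() * 2);
  for (R_xlen_t i = 0; i < keys.size(); ++i) {
    if (STRING_ELT(keys, i) == NA_STRING)
      stop("k-mer keys must not contain NA");
    if (LENGTH(keys[i]) != k)
      stop("k-mer key %d has length %d, expected %d", (int)(i + 1),
           LENGTH(keys[i]), k);
    uint64_t fwd, rev;
    if (!encode_kmer(CHAR(keys[i]), k, fwd, rev))
      stop("k-mer key %d contains a non-ACGT character", (int)(i + 1));
    uint64_t canon = fwd < rev ? fwd : rev;
    idx.emplace(canon, i);
  }
  return idx;
}

// Occurrence count of each key k-mer across all windows of seqs.
// [[Rcpp::export]]
NumericVector cpp_count_in_set(CharacterVector seqs, CharacterVector keys,
                               int k) {
  check_k(k);
  std::unordered_map<uint64_t, R_xlen_t> idx = key_index(keys, k);
  NumericVector out(keys.size(), 0.0);
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    if (STRING_ELT(seqs, i) == NA_STRING)
      continue;
    scan_canonical(CHAR(seqs[i]), (size_t)LENGTH(seqs[i]), k,
                   [&](uint64_t code) {
                     auto it = idx.find(code);
                     if (it != idx.end())
                       out[it->second] += 1.0;
                   });
  }
  return out;
}

// Per-group tallies: keys[i] belongs to group[i] (1-based, <= ngroups).
// occurrences mode sums window hits; distinct mode counts keys seen >= once.
// Also returns the total number of scanned windows.
// [[Rcpp::export]]
List cpp_count_by_group(CharacterVector seqs, CharacterVector keys,
                        IntegerVector group, int ngroups, int k,
                        bool distinct) {
  check_k(k);
  if (keys.size() != group.size())
    stop("keys and group must have equal length");
  // a k-mer may be listed for more than one group; chain duplicate keys
  std::unordered_map<uint64_t, R_xlen_t> idx;
  idx.reserve((size_t)keys.size() * 2);
  std::vector<R_xlen_t> nxt((size_t)keys.size(), -1);
  for (R_xlen_t i = 0; i < keys.size(); ++i) {
    if (STRING_ELT(keys, i) == NA_STRING)
      stop("k-mer keys must not contain NA");
    if (LENGTH(keys[i]) != k)
      stop("k-mer key %d has length %d, expected %d", (int)(i + 1),
           LENGTH(keys[i]), k);
    uint64_t fwd, rev;
    if (!encode_kmer(CHAR(keys[i]), k, fwd, rev))
      stop("k-mer key %d contains a non-ACGT character", (int)(i + 1));
    uint64_t canon = fwd < rev ? fwd : rev;
    auto r = idx.emplace(canon, i);
    if (!r.second) {
      R_xlen_t j = r.first->second;
      while (nxt[(size_t)j] >= 0)
        j = nxt[(size_t)j];
      nxt[(size_t)j] = i;
    }
  }
  NumericVector out(ngroups, 0.0);
  std::vector<char> seen;
  if (distinct)
    seen.assign((size_t)keys.size(), 0);
  double n_windows = 0;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    if (STRING_ELT(seqs, i) == NA_STRING)
      continue;
    scan_canonical(CHAR(seqs[i]), (size_t)LENGTH(seqs[i]), k,
                   [&](uint64_t code) {
                     ++n_windows;
                     auto it = idx.find(code);
                     if (it == idx.end())
                       return;
                     for (R_xlen_t j = it->second; j >= 0;
                          j = nxt[(size_t)j]) {
                       int g = group[j];
                       if (g < 1 || g > ngroups)
                         continue;
                       if (distinct) {
                         if (seen[(size_t)j])
                           continue;
                         seen[(size_t)j] = 1;
                       }
                       out[g - 1] += 1.0;
                     }
                   });
  }
  return List::create(_["count"] = out, _["n_windows"] = n_windows);
}

// Canonical form of full-length k-mers; NA for any window with non-ACGT
// characters or length mismatch handled in R.
// [[Rcpp::export]]
CharacterVector cpp_canonicalize(CharacterVector kmers, int k) {
  check_k(k);
  CharacterVector out(kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    if (STRING_ELT(kmers, i) == NA_STRING || LENGTH(kmers[i]) != k) {
      out[i] = NA_STRING;
      continue;
    }
    uint64_t fwd, rev;
    if (!encode_kmer(CHAR(kmers[i]), k, fwd, rev)) {
      out[i] = NA_STRING;
      continue;
    }
    out[i] = decode_kmer(fwd < rev ? fwd : rev, k);
  }
  return out;
}

// Base tallies over reads: called A/C/G/T bases, G+C bases, total characters.
// [[Rcpp::export]]
NumericVector cpp_base_stats(CharacterVector seqs) {
  double called = 0, gc = 0, total = 0;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    if (STRING_ELT(seqs, i) == NA_STRING)
      continue;
    const char *s = CHAR(seqs[i]);
    size_t n = (size_t)LENGTH(seqs[i]);
    total += (double)n;
    for (size_t j = 0; j < n; ++j) {
      int b = base2bits(s[j]);
      if (b >= 0) {
        ++called;
        if (b == 1 || b == 2)
          ++gc;
      }
    }
  }
  return NumericVector::create(_["called"] = called, _["gc"] = gc,
                               _["total"] = total);
}
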