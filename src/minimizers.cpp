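#include <Rcpp.h>
#include <cstdint>
#include <cstdio>
#include <deque>
#include <set>
#include <string>
#include <vector>

using namespace Rcpp;

// splitmix64 finalizer; standard avalanche mix
static inline uint64_t mix64(uint64_t z) {
  z += 0x9e3779b97f4a7c15ULL;
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

// seeded FNV-1a over bytes, finalized with splitmix64 for uniformity
static inline uint64_t hash_bytes(const char* s, int len, uint64_t seed) {
  uint64_t h = 1469598103934665603ULL ^ mix64(seed);
  for (int i = 0; i < len; ++i) {
    h ^= (uint64_t)(unsigned char)s[i];
    h *= 1099511628211ULL;
  }
  return mix64(h);
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

// 0-3 for ACGT, 4 for N, -1 for anything else
static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    case 'N': case 'n': return 4;
    default:  return -1;
  }
}

// canonical form: lexicographic min of the k-mer and its reverse complement
static std::string canonical(const std::string& kmer) {
  const int k = kmer.size();
  std::string rc(k, 'N');
  for (int i = 0; i < k; ++i) rc[k - 1 - i] = comp_base(kmer[i]);
  return (rc < kmer) ? rc : kmer;
}

// Collect canonical k-mers at every N-free position of an uppercased copy of
// seq, together with their hashes. Throws on non-ACGTN characters.
static void valid_kmers(const std::string& seq, int k, uint64_t seed,
                        std::vector<std::string>& kmers,
                        std::vector<uint64_t>& hashes) {
  const int n = seq.size();
  std::string up(seq);
  int last_bad = -1;  // most recent position holding N
  for (int i = 0; i < n; ++i) {
    int code = base_code(seq[i]);
    if (code < 0)
      stop("non-DNA character '%s' at position %d", std::string(1, seq[i]), i + 1);
    static const char ACGTN[] = "ACGTN";
    up[i] = ACGTN[code];
    if (code == 4) last_bad = i;
    if (i >= k - 1 && last_bad <= i - k) {
      std::string km = canonical(up.substr(i - k + 1, k));
      kmers.push_back(km);
      hashes.push_back(hash_bytes(km.data(), k, seed));
    }
  }
}

// Windowed minimizer selection over the ordered valid k-mers. Monotone-deque
// sliding minimum; ties broken toward the leftmost position. If fewer than w
// valid k-mers exist a single window spans them all.
static std::vector<int> select_minimizers(const std::vector<uint64_t>& h, int w) {
  const int m = h.size();
  std::vector<int> picked;
  if (m == 0) return picked;
  if (m < w) w = m;
  std::deque<int> dq;
  std::vector<bool> seen(m, false);
  for (int i = 0; i < m; ++i) {
    while (!dq.empty() && h[dq.back()] > h[i]) dq.pop_back();
    dq.push_back(i);
    if (dq.front() <= i - w) dq.pop_front();
    if (i >= w - 1 && !seen[dq.front()]) {
      seen[dq.front()] = true;
      picked.push_back(dq.front());
    }
  }
  return picked;
}

static std::vector<std::string> sketch_one(const std::string& seq, int k, int w,
                                           uint64_t seed) {
  std::vector<std::string> out;
  if ((int)seq.size() < k + w - 1) return out;  // too short: empty sketch
  std::vector<std::string> kmers;
  std::vector<uint64_t> hashes;
  valid_kmers(seq, k, seed, kmers, hashes);
  std::vector<int> idx = select_minimizers(hashes, w);
  std::set<std::string> uniq;
  for (int i : idx) uniq.insert(kmers[i]);
  out.assign(uniq.begin(), uniq.end());
  return out;
}

// [[Rcpp::export]]
CharacterVector minimizer_set_cpp(std::string seq, int k, int w, double seed) {
  std::vector<std::string> toks = sketch_one(seq, k, w, (uint64_t)seed);
  return wrap(toks);
}

// [[Rcpp::export]]
List sketch_pairs_cpp(CharacterVector seq1, CharacterVector seq2, int k, int w,
                      double seed) {
  const int n = seq1.size();
  List out(n);
  for (int i = 0; i < n; ++i) {
    std::set<std::string> uniq;
    if (seq1[i] != NA_STRING) {
      std::vector<std::string> a = sketch_one(as<std::string>(seq1[i]), k, w, (uint64_t)seed);
      uniq.insert(a.begin(), a.end());
    }
    if (i < seq2.size() && seq2[i] != NA_STRING) {
      std::vector<std::string> b = sketch_one(as<std::string>(seq2[i]), k, w, (uint64_t)seed);
      uniq.insert(b.begin(), b.end());
    }
    out[i] = CharacterVector(uniq.begin(), uniq.end());
  }
  return out;
}

// Hash of the literal strings (no canonicalization) as fixed-width hex so R
// can compare exactly; lexicographic order on the hex equals numeric order.
// [[Rcpp::export]]
CharacterVector hash_kmers_cpp(CharacterVector kmers, double seed) {
  const int n = kmers.size();
  CharacterVector out(n);
  char buf[17];
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(kmers[i]);
    uint64_t h = hash_bytes(s.data(), s.size(), (uint64_t)seed);
    snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)h);
    out[i] = buf;
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector canonical_kmers_cpp(CharacterVector kmers) {
  const int n = kmers.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = canonical(as<std::string>(kmers[i]));
  return out;
}
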