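// Canonical k-mer membership structures backing the shared-k-mer similarity
// kernel, the host-read screen and the marker-based read assigner.
//
// k-mers are 2-bit encoded (A=0, C=1, G=2, T=3) into a 64-bit word, so k is
// limited to 31.  Canonicalisation keeps the smaller of a k-mer's code and
// the code of its reverse complement, making matching strand-insensitive.
// Windows containing any non-ACGT character are skipped entirely.

#include <Rcpp.h>
#include <unordered_set>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <string>

using namespace Rcpp;

typedef std::unordered_set<uint64_t> KmerSet;
typedef std::unordered_map<uint64_t, int> KmerMap;

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

// Applies fn(code) to every (optionally canonical) k-mer of seq.
template <typename F>
static void for_each_kmer(const char *seq, size_t len, int k, bool canonical,
                          F fn) {
  if ((size_t)k > len) return;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t fwd = 0, rev = 0;
  int valid = 0;  // length of the current run of ACGT bases
  const int shift_rc = 2 * (k - 1);
  for (size_t i = 0; i < len; ++i) {
    int c = base_code(seq[i]);
    if (c < 0) { valid = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)c) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - c) << shift_rc);
    if (++valid >= k) {
      uint64_t code = canonical ? std::min(fwd, rev) : fwd;
      fn(code);
    }
  }
}

static void check_k(int k) {
  if (k < 1 || k > 31)
    stop("k must be between 1 and 31 for the 2-bit k-mer encoding");
}

// [[Rcpp::export]]
SEXP cpp_kmer_set_build(CharacterVector seqs, int k, bool canonical) {
  check_k(k);
  KmerSet *set = new KmerSet();
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const char *s = CHAR(STRING_ELT(seqs, i));
    for_each_kmer(s, std::strlen(s), k, canonical,
                  [&](uint64_t code) { set->insert(code); });
  }
  XPtr<KmerSet> ptr(set, true);
  return ptr;
}

// [[Rcpp::export]]
double cpp_kmer_set_size(SEXP xp) {
  XPtr<KmerSet> ptr(xp);
  return (double)ptr->size();
}

// Number of DISTINCT (canonical) k-mers of each read found in the set.
// [[Rcpp::export]]
IntegerVector cpp_shared_kmer_counts(CharacterVector reads, SEXP xp, int k,
                                     bool canonical) {
  check_k(k);
  XPtr<KmerSet> ptr(xp);
  IntegerVector out(reads.size());
  std::unordered_set<uint64_t> seen;
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    seen.clear();
    const char *s = CHAR(STRING_ELT(reads, i));
    for_each_kmer(s, std::strlen(s), k, canonical, [&](uint64_t code) {
      if (ptr->count(code)) seen.insert(code);
    });
    out[i] = (int)seen.size();
  }
  return out;
}

static std::string decode_kmer(uint64_t code, int k) {
  static const char bases[] = "ACGT";
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = bases[code & 3ULL];
    code >>= 2;
  }
  return s;
}

// Dump the set as sorted k-mer strings (text save/load of an index).
// [[Rcpp::export]]
CharacterVector cpp_kmer_set_dump(SEXP xp, int k) {
  check_k(k);
  XPtr<KmerSet> ptr(xp);
  std::vector<uint64_t> codes(ptr->begin(), ptr->end());
  std::sort(codes.begin(), codes.end());
  CharacterVector out(codes.size());
  for (size_t i = 0; i < codes.size(); ++i)
    out[i] = decode_kmer(codes[i], k);
  return out;
}

// k-mer -> integer label map (marker database).  Returns the map plus the
// number of k-mers claimed by two different labels (collisions); collided
// k-mers are dropped from the map so callers can rejection-sample.
// [[Rcpp::export]]
List cpp_kmer_map_build(CharacterVector seqs, IntegerVector labels, int k,
                        bool canonical) {
  check_k(k);
  if (seqs.size() != labels.size())
    stop("seqs and labels must have equal length");
  KmerMap *map = new KmerMap();
  std::unordered_set<uint64_t> collided;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const char *s = CHAR(STRING_ELT(seqs, i));
    int lab = labels[i];
    for_each_kmer(s, std::strlen(s), k, canonical, [&](uint64_t code) {
      if (collided.count(code)) return;
      auto it = map->find(code);
      if (it == map->end()) {
        (*map)[code] = lab;
      } else if (it->second != lab) {
        map->erase(it);
        collided.insert(code);
      }
    });
  }
  XPtr<KmerMap> ptr(map, true);
  return List::create(_["ptr"] = ptr,
                      _["n_kmers"] = (double)map->size(),
                      _["n_collisions"] = (double)collided.size());
}

// Assign each read to the unique label whose k-mers it shares (>= min_hits
// distinct shared k-mers).  0 = unassigned, -1 = matches more than one label.
// [[Rcpp::export]]
IntegerVector cpp_kmer_map_assign(CharacterVector reads, SEXP xp, int k,
                                  bool canonical, int min_hits) {
  check_k(k);
  XPtr<KmerMap> ptr(xp);
  IntegerVector out(reads.size());
  std::unordered_set<uint64_t> seen;
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    seen.clear();
    int lab = 0, hits = 0;
    bool conflict = false;
    const char *s = CHAR(STRING_ELT(reads, i));
    for_each_kmer(s, std::strlen(s), k, canonical, [&](uint64_t code) {
      auto it = ptr->find(code);
      if (it == ptr->end() || seen.count(code)) return;
      seen.insert(code);
      if (lab == 0) lab = it->second;
      else if (lab != it->second) conflict = true;
      ++hits;
    });
    out[i] = conflict ? -1 : (hits >= min_hits ? lab : 0);
  }
  return out;
}
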