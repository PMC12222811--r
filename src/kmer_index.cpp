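// Colored k-mer index over a set of replicons.
//
// Canonical k-mers (lexicographic min of a k-mer and its reverse
// complement) are packed into 64-bit 2-bit codes, which caps k at 31.
// The index stores, per canonical k-mer, the replicon color set as a
// 64-bit mask (hence at most 64 replicons per genome) and every
// occurrence as (replicon, position, orientation). Positions are
// 0-based; orientation records whether the genome k-mer equals its
// canonical form, so that implied read-start positions can be
// reconstructed for multiread location counting.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

static inline int base2code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;  // N and other ambiguity codes break the k-mer run
  }
}

struct Occ {
  int32_t rep;
  int32_t pos;
  bool fwd;  // genome k-mer equals its canonical form
};

// Open-addressing hash table from canonical k-mer code to color mask.
// Canonical codes use at most 62 bits, so ~0 is a safe empty sentinel.
// Linear probing over a power-of-two table kept under half load: color
// lookup is the innermost loop of read classification.
struct FlatColorMap {
  static constexpr uint64_t EMPTY = ~0ULL;
  std::vector<uint64_t> keys;
  std::vector<uint64_t> vals;
  uint64_t mask;
  size_t n;

  FlatColorMap() : keys(16, EMPTY), vals(16, 0), mask(15), n(0) {}

  static inline uint64_t hash(uint64_t x) {
    x ^= x >> 33; x *= 0xff51afd7ed558ccdULL;
    x ^= x >> 33; x *= 0xc4ceb9fe1a85ec53ULL;
    x ^= x >> 33; return x;
  }

  void grow() {
    std::vector<uint64_t> ok(std::move(keys)), ov(std::move(vals));
    size_t cap = ok.size() * 2;
    keys.assign(cap, EMPTY);
    vals.assign(cap, 0);
    mask = cap - 1;
    for (size_t i = 0; i < ok.size(); ++i)
      if (ok[i] != EMPTY) {
        uint64_t j = hash(ok[i]) & mask;
        while (keys[j] != EMPTY) j = (j + 1) & mask;
        keys[j] = ok[i]; vals[j] = ov[i];
      }
  }

  void or_insert(uint64_t key, uint64_t bit) {
    if (2 * (n + 1) > keys.size()) grow();
    uint64_t j = hash(key) & mask;
    while (keys[j] != EMPTY && keys[j] != key) j = (j + 1) & mask;
    if (keys[j] == EMPTY) { keys[j] = key; ++n; }
    vals[j] |= bit;
  }

  // returns 0 when absent (color masks are never 0 for stored k-mers)
  inline uint64_t find(uint64_t key) const {
    uint64_t j = hash(key) & mask;
    while (keys[j] != EMPTY) {
      if (keys[j] == key) return vals[j];
      j = (j + 1) & mask;
    }
    return 0;
  }
};

struct KmerIndex {
  int k;
  int n_rep;
  std::vector<int64_t> rep_len;
  FlatColorMap colors;                                     // canonical -> color mask
  std::unordered_map<uint64_t, std::vector<Occ> > occs;    // canonical -> occurrences
};

// Call f(start, canonical_code, is_forward) for every k-mer window of s
// that contains no ambiguous base. Rolling 2-bit encoding of both strands.
template <typename F>
static void for_each_kmer(const char* s, int64_t n, int k, F f) {
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  const int shift = 2 * (k - 1);
  uint64_t fwd = 0, rc = 0;
  int run = 0;
  for (int64_t i = 0; i < n; ++i) {
    int c = base2code(s[i]);
    if (c < 0) { run = 0; fwd = 0; rc = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)c) & mask;
    rc = (rc >> 2) | ((uint64_t)(3 - c) << shift);
    if (++run >= k) {
      bool is_fwd = fwd <= rc;
      f(i - k + 1, is_fwd ? fwd : rc, is_fwd);
    }
  }
}

// [[Rcpp::export]]
SEXP cpp_index_build(CharacterVector seqs, int k) {
  if (k < 11 || k > 31 || k % 2 == 0)
    stop("k must be odd and in [11, 31]");
  if (seqs.size() > 64)
    stop("at most 64 replicons are supported");
  XPtr<KmerIndex> ptr(new KmerIndex(), true);
  ptr->k = k;
  ptr->n_rep = seqs.size();
  for (int r = 0; r < seqs.size(); ++r) {
    const char* s = CHAR(STRING_ELT(seqs, r));
    int64_t n = LENGTH(STRING_ELT(seqs, r));
    ptr->rep_len.push_back(n);
    if (n < k)
      stop("replicon %d is shorter than k = %d", r + 1, k);
    uint64_t col = 1ULL << r;
    for_each_kmer(s, n, k, [&](int64_t pos, uint64_t canon, bool fwd) {
      ptr->colors.or_insert(canon, col);
      ptr->occs[canon].push_back(Occ{(int32_t)r, (int32_t)pos, fwd});
    });
  }
  return ptr;
}

// [[Rcpp::export]]
List cpp_index_stats(SEXP ptr_) {
  XPtr<KmerIndex> ptr(ptr_);
  double npos = 0;
  for (auto& kv : ptr->occs) npos += kv.second.size();
  return List::create(_["k"] = ptr->k,
                      _["n_replicons"] = ptr->n_rep,
                      _["n_kmers"] = (double)ptr->colors.n,
                      _["n_positions"] = npos);
}

static IntegerVector mask_to_reps(uint64_t m) {
  std::vector<int> out;
  for (int b = 0; b < 64; ++b)
    if (m & (1ULL << b)) out.push_back(b + 1);
  return wrap(out);
}

// Color set (1-based replicon indices) of each query k-mer string;
// integer(0) for k-mers that are absent, contain N, or have wrong length.
// [[Rcpp::export]]
List cpp_kmer_colors(SEXP ptr_, CharacterVector kmers) {
  XPtr<KmerIndex> ptr(ptr_);
  int k = ptr->k;
  List out(kmers.size());
  for (int i = 0; i < kmers.size(); ++i) {
    const char* s = CHAR(STRING_ELT(kmers, i));
    int64_t n = LENGTH(STRING_ELT(kmers, i));
    uint64_t found = 0;
    bool any = false;
    if (n == k) {
      for_each_kmer(s, n, k, [&](int64_t, uint64_t canon, bool) {
        uint64_t cm = ptr->colors.find(canon);
        if (cm) { found = cm; any = true; }
      });
    }
    out[i] = any ? mask_to_reps(found) : IntegerVector(0);
  }
  return out;
}

// Pseudoalign a batch of reads. For each read, collect the color sets of
// its k-mers that hit the index; the replicon set is the intersection of
// the hit color sets, falling back to the colors supported by >= tau of
// the hit k-mers when the intersection is empty (chimeric junction
// guard). status: 0 unmapped, 1 uniread, 2 multiread. uni_rep carries
// the single (1-based) replicon of each uniread; the sets list is
// materialized for multireads only (NULL elsewhere) to keep per-read
// allocation off the uniread fast path.
// [[Rcpp::export]]
List cpp_pseudoalign(SEXP ptr_, CharacterVector reads, double tau) {
  XPtr<KmerIndex> ptr(ptr_);
  int k = ptr->k, n_rep = ptr->n_rep;
  int m = reads.size();
  IntegerVector status(m);
  IntegerVector uni_rep(m);
  List sets(m);
  std::vector<int> colcount(n_rep);
  for (int i = 0; i < m; ++i) {
    const char* s = CHAR(STRING_ELT(reads, i));
    int64_t n = LENGTH(STRING_ELT(reads, i));
    std::fill(colcount.begin(), colcount.end(), 0);
    int n_hit = 0;
    uint64_t inter = ~0ULL;
    for_each_kmer(s, n, k, [&](int64_t, uint64_t canon, bool) {
      uint64_t cm = ptr->colors.find(canon);
      if (!cm) return;
      ++n_hit;
      inter &= cm;
      while (cm) {
        int b = __builtin_ctzll(cm);
        ++colcount[b];
        cm &= cm - 1;
      }
    });
    if (n_hit == 0) continue;  // status 0, unmapped
    uint64_t mask = inter;
    if (mask == 0) {
      double thr = tau * n_hit;
      for (int b = 0; b < n_rep; ++b)
        if (colcount[b] >= thr) mask |= 1ULL << b;
    }
    int nc = __builtin_popcountll(mask);
    if (nc == 1) {
      status[i] = 1;
      uni_rep[i] = __builtin_ctzll(mask) + 1;
    } else if (nc > 1) {
      status[i] = 2;
      sets[i] = mask_to_reps(mask);
    }
  }
  return List::create(_["status"] = status, _["uni_rep"] = uni_rep,
                      _["sets"] = sets);
}

// Count distinct candidate alignment locations of each read on each
// replicon. Every k-mer occurrence votes for an implied read-start
// position (strand-aware); votes are clustered per replicon with a merge
// window of the read length, and a cluster whose best-supported start
// gathers >= tau_loc of the read's hitting k-mers counts as one location.
// [[Rcpp::export]]
IntegerMatrix cpp_locate(SEXP ptr_, CharacterVector reads, double tau_loc) {
  XPtr<KmerIndex> ptr(ptr_);
  int k = ptr->k, n_rep = ptr->n_rep;
  int m = reads.size();
  IntegerMatrix M(m, n_rep);
  std::vector<std::vector<int64_t> > votes(n_rep);
  for (int i = 0; i < m; ++i) {
    const char* s = CHAR(STRING_ELT(reads, i));
    int64_t len = LENGTH(STRING_ELT(reads, i));
    for (auto& v : votes) v.clear();
    int n_hit = 0;
    for_each_kmer(s, len, k, [&](int64_t off, uint64_t canon, bool rfwd) {
      auto it = ptr->occs.find(canon);
      if (it == ptr->occs.end()) return;
      ++n_hit;
      for (const Occ& o : it->second) {
        // same orientation: read aligns forward, start = pos - off;
        // opposite: reverse-complemented read aligns, its k-mer at
        // offset len - k - off sits at pos.
        int64_t start = (rfwd == o.fwd) ? (o.pos - off)
                                        : (o.pos - (len - k - off));
        votes[o.rep].push_back(start);
      }
    });
    if (n_hit == 0) continue;
    double thr = tau_loc * n_hit;
    for (int r = 0; r < n_rep; ++r) {
      std::vector<int64_t>& v = votes[r];
      if (v.empty()) continue;
      std::sort(v.begin(), v.end());
      int n_loc = 0;
      size_t j = 0;
      while (j < v.size()) {
        int64_t anchor = v[j];
        // within one cluster, support is the best single implied start
        // (a k-mer can vote several nearby starts in tandem repeats)
        int best = 0, cur = 0;
        int64_t curstart = v[j];
        while (j < v.size() && v[j] - anchor < len) {
          if (v[j] == curstart) {
            ++cur;
          } else {
            if (cur > best) best = cur;
            curstart = v[j];
            cur = 1;
          }
          ++j;
        }
        if (cur > best) best = cur;
        if (best >= thr) ++n_loc;
      }
      M(i, r) = n_loc;
    }
  }
  return M;
}
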