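#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <algorithm>
#include <cstdint>
#include <string>
#include <vector>

using namespace Rcpp;

// ---- basic DNA helpers -----------------------------------------------------

static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1;  // N and anything else: never matches
  }
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

static std::string revcomp(const std::string &s) {
  std::string out(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i)
    out[s.size() - 1 - i] = comp_base(s[i]);
  return out;
}

// mismatch between two characters; any non-ACGT base is a mismatch
static inline bool is_mismatch(char a, char b) {
  return a != b || base_code(a) < 0;
}

// Hamming distance with early abort once `cap` is exceeded (returns cap + 1)
static int hamming_capped(const char *a, const char *b, int len, int cap) {
  int mm = 0;
  for (int i = 0; i < len; ++i) {
    if (is_mismatch(a[i], b[i])) {
      if (++mm > cap) return cap + 1;
    }
  }
  return mm;
}

// ---- seed index ------------------------------------------------------------

// Exact k-mer index over the forward strand of a set of target sequences.
// Postings pack (target id, 0-based position) into one 64-bit word.
struct SeedIndex {
  int k;
  std::vector<std::string> names;
  std::vector<std::string> seqs;
  std::unordered_map<uint64_t, std::vector<uint64_t>> postings;
};

static inline uint64_t pack_post(uint32_t tid, uint32_t pos) {
  return (static_cast<uint64_t>(tid) << 32) | pos;
}

// Rolling k-mer encoder: returns false when the window contains a non-ACGT
// base. `code` is valid only when the return value is true.
struct KmerRoller {
  int k, valid;
  uint64_t code, mask;
  explicit KmerRoller(int k_) : k(k_), valid(0), code(0) {
    mask = (k_ >= 32) ? ~uint64_t(0) : ((uint64_t(1) << (2 * k_)) - 1);
  }
  bool push(char c) {
    int b = base_code(c);
    if (b < 0) { valid = 0; code = 0; return false; }
    code = ((code << 2) | uint64_t(b)) & mask;
    if (valid < k) ++valid;
    return valid == k;
  }
};

// [[Rcpp::export]]
SEXP fa_build_index(CharacterVector names, CharacterVector seqs, int k) {
  if (k < 1 || k > 31) stop("seed length k must be in [1, 31]");
  SeedIndex *idx = new SeedIndex();
  idx->k = k;
  for (R_xlen_t t = 0; t < seqs.size(); ++t) {
    std::string s = as<std::string>(seqs[t]);
    idx->names.push_back(as<std::string>(names[t]));
    idx->seqs.push_back(s);
    if ((int)s.size() < k)
      stop("target '%s' (%d nt) is shorter than the seed length k = %d",
           idx->names[t].c_str(), (int)s.size(), k);
    KmerRoller roll(k);
    for (size_t i = 0; i < s.size(); ++i) {
      if (roll.push(s[i]))
        idx->postings[roll.code].push_back(pack_post((uint32_t)t, (uint32_t)(i + 1 - k)));
    }
  }
  XPtr<SeedIndex> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export]]
List fa_index_info(SEXP xp) {
  XPtr<SeedIndex> idx(xp);
  return List::create(_["k"] = idx->k,
                      _["names"] = wrap(idx->names),
                      _["lengths"] = wrap([&] {
                        std::vector<int> L;
                        for (auto &s : idx->seqs) L.push_back((int)s.size());
                        return L;
                      }()));
}

static uint64_t encode_kmer(const std::string &s, bool &ok) {
  KmerRoller roll((int)s.size());
  ok = false;
  bool full = false;
  for (char c : s) full = roll.push(c);
  ok = full;
  return roll.code;
}

// Exact k-mer lookup. Forward postings report loci where `kmer` matches the
// target's forward strand; the minus-strand postings report loci whose
// reverse complement equals `kmer` (position = leftmost base on the target).
// [[Rcpp::export]]
List fa_lookup(SEXP xp, std::string kmer) {
  XPtr<SeedIndex> idx(xp);
  if ((int)kmer.size() != idx->k) stop("query length must equal index k");
  std::vector<int> tid, pos;
  std::vector<std::string> strand;
  bool ok = false;
  uint64_t code = encode_kmer(kmer, ok);
  if (ok) {
    auto it = idx->postings.find(code);
    if (it != idx->postings.end())
      for (uint64_t p : it->second) {
        tid.push_back((int)(p >> 32) + 1);
        pos.push_back((int)(p & 0xffffffffu) + 1);
        strand.push_back("+");
      }
  }
  std::string rc = revcomp(kmer);
  uint64_t rcode = encode_kmer(rc, ok);
  if (ok) {
    auto it = idx->postings.find(rcode);
    if (it != idx->postings.end())
      for (uint64_t p : it->second) {
        tid.push_back((int)(p >> 32) + 1);
        pos.push_back((int)(p & 0xffffffffu) + 1);
        strand.push_back("-");
      }
  }
  return List::create(_["target"] = wrap(tid), _["pos"] = wrap(pos),
                      _["strand"] = wrap(strand));
}

// ---- end-to-end ungapped alignment ----------------------------------------

struct Hit {
  int tid, pos, mm;   // pos 0-based
  char strand;
  bool operator<(const Hit &o) const {
    if (mm != o.mm) return mm < o.mm;
    if (tid != o.tid) return tid < o.tid;
    if (pos != o.pos) return pos < o.pos;
    return strand < o.strand;
  }
};

static void verify_placement(const SeedIndex &idx, const std::string &q,
                             int tid, long pos, char strand, int max_mm,
                             std::unordered_set<uint64_t> &seen,
                             std::vector<Hit> &hits) {
  const std::string &t = idx.seqs[tid];
  if (pos < 0 || pos + (long)q.size() > (long)t.size()) return;
  uint64_t key = (uint64_t)tid << 40 | (uint64_t)pos << 8 | (uint64_t)(strand == '+');
  if (!seen.insert(key).second) return;
  int mm = hamming_capped(q.c_str(), t.c_str() + pos, (int)q.size(), max_mm);
  if (mm <= max_mm) hits.push_back(Hit{tid, (int)pos, mm, strand});
}

static void seed_candidates(const SeedIndex &idx, const std::string &q,
                            char strand, int max_mm,
                            std::unordered_set<uint64_t> &seen,
                            std::vector<Hit> &hits) {
  int L = (int)q.size(), k = idx.k;
  // seeds at both termini plus the middle: any ungapped placement with few
  // mismatches keeps at least one seed exact in typical reads
  std::vector<int> offs;
  offs.push_back(0);
  if (L - k > 0) offs.push_back(L - k);
  if ((L - k) / 2 > 0 && (L - k) / 2 < L - k) offs.push_back((L - k) / 2);
  for (int off : offs) {
    bool ok = false;
    uint64_t code = encode_kmer(q.substr(off, k), ok);
    if (!ok) continue;
    auto it = idx.postings.find(code);
    if (it == idx.postings.end()) continue;
    for (uint64_t p : it->second) {
      int tid = (int)(p >> 32);
      long pos = (long)(p & 0xffffffffu) - off;
      verify_placement(idx, q, tid, pos, strand, max_mm, seen, hits);
    }
  }
}

// brute-force fallback for reads shorter than the seed length
static void brute_candidates(const SeedIndex &idx, const std::string &q,
                             char strand, int max_mm,
                             std::unordered_set<uint64_t> &seen,
                             std::vector<Hit> &hits) {
  for (size_t tid = 0; tid < idx.seqs.size(); ++tid) {
    const std::string &t = idx.seqs[tid];
    if (q.size() > t.size()) continue;
    for (long pos = 0; pos + q.size() <= t.size(); ++pos)
      verify_placement(idx, q, (int)tid, pos, strand, max_mm, seen, hits);
  }
}

// Align each read end-to-end (ungapped) against all indexed targets on both
// strands; every placement with <= max_mm mismatches, ranked by mismatches
// then (target, pos), truncated to max_hits.
// [[Rcpp::export]]
List fa_align(SEXP xp, CharacterVector reads, int max_mm, int max_hits) {
  XPtr<SeedIndex> idx(xp);
  std::vector<int> out_read, out_tid, out_pos, out_mm;
  std::vector<std::string> out_strand;
  LogicalVector truncated(reads.size());
  IntegerVector n_hits(reads.size());
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    std::string fwd = as<std::string>(reads[r]);
    std::string rev = revcomp(fwd);
    std::vector<Hit> hits;
    std::unordered_set<uint64_t> seen_f, seen_r;
    if ((int)fwd.size() < idx->k) {
      brute_candidates(*idx, fwd, '+', max_mm, seen_f, hits);
      brute_candidates(*idx, rev, '-', max_mm, seen_r, hits);
    } else {
      seed_candidates(*idx, fwd, '+', max_mm, seen_f, hits);
      seed_candidates(*idx, rev, '-', max_mm, seen_r, hits);
    }
    std::sort(hits.begin(), hits.end());
    n_hits[r] = (int)hits.size();
    truncated[r] = (int)hits.size() > max_hits;
    int keep = std::min((int)hits.size(), max_hits);
    for (int i = 0; i < keep; ++i) {
      out_read.push_back((int)r + 1);
      out_tid.push_back(hits[i].tid + 1);
      out_pos.push_back(hits[i].pos + 1);
      out_mm.push_back(hits[i].mm);
      out_strand.push_back(std::string(1, hits[i].strand));
    }
  }
  return List::create(_["read"] = wrap(out_read), _["target"] = wrap(out_tid),
                      _["pos"] = wrap(out_pos), _["strand"] = wrap(out_strand),
                      _["mismatches"] = wrap(out_mm),
                      _["n_hits"] = n_hits, _["truncated"] = truncated);
}

// ---- one-gap rescue --------------------------------------------------------

// Best mismatch count for placing `q` on target `t` starting at `a` with one
// gap of size g: deletion-from-read (target consumes L + g bases) when
// del = true, insertion-in-read (target consumes L - g) otherwise.
static int one_gap_best(const std::string &q, const std::string &t, long a,
                        int g, bool del, int cap) {
  int L = (int)q.size();
  long span = del ? (long)L + g : (long)L - g;
  if (a < 0 || a + span > (long)t.size() || span < 1) return cap + 1;
  // pref[i] = mismatches of q[0..i-1] vs t[a..a+i-1]; only splits that fit
  // inside the consumed target span are ever read
  int pref_max = del ? L : L - g;
  std::vector<int> pref(L + 1, 0);
  for (int i = 0; i < pref_max; ++i)
    pref[i + 1] = pref[i] + (is_mismatch(q[i], t[a + i]) ? 1 : 0);
  int best = cap + 1;
  if (del) {
    // split i in 1..L-1: q[i..L-1] vs t[a+i+g ..]
    std::vector<int> suf(L + 1, 0);
    for (int i = L - 1; i >= 0; --i)
      suf[i] = suf[i + 1] + (is_mismatch(q[i], t[a + i + g]) ? 1 : 0);
    for (int i = 1; i < L; ++i)
      best = std::min(best, pref[i] + suf[i]);
  } else {
    // split i in 1..L-g-1: q[i+g..L-1] vs t[a+i ..]
    std::vector<int> suf(L + 1, 0);
    for (int i = L - 1; i >= g; --i)
      suf[i] = suf[i + 1] + (is_mismatch(q[i], t[a + i - g]) ? 1 : 0);
    for (int i = 1; i + g < L; ++i)
      best = std::min(best, pref[i] + suf[i + g]);
  }
  return best;
}

// Can each read be placed end-to-end with exactly one insertion or deletion
// of 1..max_gap bases (and <= max_mm substitutions)? Anchored at exact
// terminal seeds on either strand.
// [[Rcpp::export]]
LogicalVector fa_gap_rescue(SEXP xp, CharacterVector reads, int max_mm,
                            int max_gap) {
  XPtr<SeedIndex> idx(xp);
  int k = idx->k;
  LogicalVector rescued(reads.size());
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    std::string fwd = as<std::string>(reads[r]);
    if ((int)fwd.size() < k + 1) { rescued[r] = false; continue; }
    bool found = false;
    for (int s = 0; s < 2 && !found; ++s) {
      const std::string q = (s == 0) ? fwd : revcomp(fwd);
      int L = (int)q.size();
      for (int anchor = 0; anchor < 2 && !found; ++anchor) {
        int off = (anchor == 0) ? 0 : L - k;
        bool ok = false;
        uint64_t code = encode_kmer(q.substr(off, k), ok);
        if (!ok) continue;
        auto it = idx->postings.find(code);
        if (it == idx->postings.end()) continue;
        for (uint64_t p : it->second) {
          int tid = (int)(p >> 32);
          long seedpos = (long)(p & 0xffffffffu);
          const std::string &t = idx->seqs[tid];
          for (int g = 1; g <= max_gap && !found; ++g) {
            for (int del = 0; del < 2 && !found; ++del) {
              long a;
              if (anchor == 0) a = seedpos;               // start fixed
              else a = seedpos + k - (del ? (long)L + g : (long)L - g); // end fixed
              if (one_gap_best(q, t, a, g, del == 1, max_mm) <= max_mm)
                found = true;
            }
          }
          if (found) break;
        }
      }
    }
    rescued[r] = found;
  }
  return rescued;
}

// ---- scan reference strings against an index of short reads ----------------

// The index holds short sequences (reads and/or their reverse complements);
// each `refs` string is scanned with its own k-mers and every anchored
// placement of an indexed read fully inside the ref is verified (ungapped,
// <= max_mm). Used to map junction-library sequences against UUM reads
// without indexing the (much larger) library.
// [[Rcpp::export]]
List fa_scan_refs(SEXP xp, CharacterVector refs, int max_mm) {
  XPtr<SeedIndex> idx(xp);
  int k = idx->k;
  std::vector<int> out_ref, out_tid, out_pos, out_mm;
  for (R_xlen_t ri = 0; ri < refs.size(); ++ri) {
    std::string ref = as<std::string>(refs[ri]);
    if ((int)ref.size() < k) continue;
    std::unordered_set<uint64_t> seen;
    KmerRoller roll(k);
    for (size_t i = 0; i < ref.size(); ++i) {
      if (!roll.push(ref[i])) continue;
      auto it = idx->postings.find(roll.code);
      if (it == idx->postings.end()) continue;
      long kpos = (long)i + 1 - k;
      for (uint64_t p : it->second) {
        int tid = (int)(p >> 32);
        long off = (long)(p & 0xffffffffu);
        long pos = kpos - off;
        const std::string &q = idx->seqs[tid];
        if (pos < 0 || pos + (long)q.size() > (long)ref.size()) continue;
        uint64_t key = (uint64_t)tid << 32 | (uint64_t)pos;
        if (!seen.insert(key).second) continue;
        int mm = hamming_capped(q.c_str(), ref.c_str() + pos, (int)q.size(), max_mm);
        if (mm <= max_mm) {
          out_ref.push_back((int)ri + 1);
          out_tid.push_back(tid + 1);
          out_pos.push_back((int)pos + 1);
          out_mm.push_back(mm);
        }
      }
    }
  }
  return List::create(_["ref"] = wrap(out_ref), _["target"] = wrap(out_tid),
                      _["pos"] = wrap(out_pos), _["mismatches"] = wrap(out_mm));
}

// pairwise Hamming mismatch counts for equal-length string pairs
// [[Rcpp::export]]
IntegerVector fa_hamming(CharacterVector a, CharacterVector b) {
  if (a.size() != b.size()) stop("a and b must have equal length");
  IntegerVector out(a.size());
  for (R_xlen_t i = 0; i < a.size(); ++i) {
    std::string x = as<std::string>(a[i]), y = as<std::string>(b[i]);
    if (x.size() != y.size()) stop("strings at position %d differ in length", (int)i + 1);
    out[i] = hamming_capped(x.c_str(), y.c_str(), (int)x.size(), (int)x.size());
  }
  return out;
}
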