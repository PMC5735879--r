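#ifndef SEEDOVERLAP_CORE_H
#define SEEDOVERLAP_CORE_H

#include <array>
#include <cstdint>
#include <cstring>
#include <string>
#include <vector>
#include <unordered_map>
#include <algorithm>
#include <cmath>

namespace seedoverlap {

// base codes: A=0, C=1, G=2, T=3; complement = 3 - code
inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

inline char code_base(int code) {
  static const char b[4] = {'A', 'C', 'G', 'T'};
  return b[code & 3];
}

// byte-per-base working codes for one read, both strands
struct CodedRead {
  int len = 0;
  std::vector<uint8_t> fwd;  // forward strand codes
  std::vector<uint8_t> rev;  // reverse-complement strand codes
};

// non-ACGT characters become 'A' (code 0); count returned via n_replaced
inline CodedRead code_read(const std::string& s, int* n_replaced = nullptr) {
  CodedRead cr;
  cr.len = (int)s.size();
  cr.fwd.resize(cr.len);
  cr.rev.resize(cr.len);
  int bad = 0;
  for (int i = 0; i < cr.len; ++i) {
    int c = base_code(s[i]);
    if (c < 0) { c = 0; ++bad; }
    cr.fwd[i] = (uint8_t)c;
  }
  for (int i = 0; i < cr.len; ++i)
    cr.rev[i] = (uint8_t)(3 - cr.fwd[cr.len - 1 - i]);
  if (n_replaced) *n_replaced = bad;
  return cr;
}

// k-mer occurrence: read id (0-based), 0-based position on the annotated
// strand, strand 0 = forward, 1 = reverse complement
struct Occ {
  int32_t rid;
  int32_t pos;
  uint8_t strand;
};

struct KmerIndex {
  int k;
  int max_kmer_count;
  int min_kmer_count;
  int n_reads;
  std::size_t n_positions = 0;       // total k-mer positions scanned
  std::size_t n_filtered_high = 0;   // k-mer values dropped by the ceiling
  std::size_t n_filtered_low = 0;    // k-mer values dropped by the floor
  std::unordered_map<uint64_t, std::vector<Occ>> occ;
};

// rolling k-mer enumeration over a coded strand; calls f(value, pos)
template <typename F>
inline void for_each_kmer(const std::vector<uint8_t>& codes, int k, F f) {
  const int n = (int)codes.size();
  if (n < k) return;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  uint64_t val = 0;
  for (int i = 0; i < n; ++i) {
    val = ((val << 2) | codes[i]) & mask;
    if (i >= k - 1) f(val, i - k + 1);
  }
}

inline uint64_t kmer_value(const std::string& s) {
  uint64_t v = 0;
  for (char c : s) {
    int code = base_code(c);
    v = (v << 2) | (uint64_t)(code < 0 ? 0 : code);
  }
  return v;
}

// one seed match: k-mer start on query forward strand / chosen ref strand
struct Match {
  int32_t qpos;
  int32_t rpos;
};

struct Cluster {
  int left;        // index into V (0-based, inclusive)
  int right;       // index into V (0-based, inclusive)
  int matched_bp;  // query bases covered by the union of member k-mers
  int hits;        // member count
};

// adjacent-consistency predicate: both coordinates non-decreasing and the
// diagonal drift bounded by max_shift relative to the larger gap
inline bool consistent(const Match& a, const Match& b, double max_shift) {
  const int dq = b.qpos - a.qpos;
  const int dr = b.rpos - a.rpos;
  if (dq < 0 || dr < 0) return false;
  const int diff = dq > dr ? dq - dr : dr - dq;
  const int mx = dq > dr ? dq : dr;
  return (double)diff <= max_shift * (double)mx;
}

// greedy left-to-right partition of V into maximal consistent runs
std::vector<Cluster> cluster_matches(const std::vector<Match>& V, int k,
                                     double max_shift);

// mu - 3*sigma floor on seed counts: L trials, p = (1-e)^(2k)
inline double binom_threshold(double L, double e, int k) {
  const double p = std::pow(1.0 - e, 2.0 * k);
  const double mu = L * p;
  return mu - 3.0 * std::sqrt(L * p * (1.0 - p));
}

// configuration-symmetric alignment-length estimate from seed bounds:
// chained span plus the shorter overhang on each side
inline double align_length(int q_l, int q_r, int r_l, int r_r, int qlen,
                           int rlen) {
  const double span =
      std::max((double)(q_r - q_l), (double)(r_r - r_l));
  const double left = std::min((double)q_l, (double)r_l);
  const double right =
      std::min((double)(qlen - q_r), (double)(rlen - r_r));
  return span + left + right;
}

struct MaxBounds {
  int query_start, query_end, ref_start, ref_end;
};

MaxBounds max_bounds(int q_l, int r_l, int q_r, int r_r, int qlen, int rlen,
                     double max_shift);

struct PairParams {
  int k = 16;
  int small_k = 12;
  double max_shift = 0.2;
  double error_rate = 0.15;
  int max_kmer_count = 10000;
};

// per-pair result; coordinates on the query forward strand and on the
// oriented (possibly reverse-complemented) reference strand
struct PairResult {
  bool found = false;
  bool reclustered = false;
  bool cluster_pass = false;
  // selected cluster seed bounds (k-mer start/end positions)
  int q_l = 0, r_l = 0, q_r = 0, r_r = 0;
  int cluster_hits = 0, cluster_bp = 0;
  double cluster_threshold = 0.0;
  MaxBounds window{0, 0, 0, 0};
  // final overlap bounds (half-open)
  int q_start = 0, q_end = 0, r_start = 0, r_end = 0;
  int total_hits = 0;        // deduplicated k'-mer matches in the final region
  double final_threshold = 0.0;
  int score = 0;             // matched bp (cluster k-mers + accepted k'-mers)
  double identity = 0.0;     // seed-density identity estimate
};

// full per-pair pipeline given the seed matches for the chosen strand
PairResult pair_pipeline(const std::vector<uint8_t>& q,
                         const std::vector<uint8_t>& r,
                         std::vector<Match> V, const PairParams& par);

KmerIndex* build_index(const std::vector<std::string>& seqs, int k, int maxc,
                       int minc);

struct PairMatches {
  int ref_id;
  int strand;
  std::vector<Match> V;
};

std::vector<PairMatches> collect_matches(const KmerIndex& idx,
                                         const std::vector<uint8_t>& qfwd,
                                         int qid, bool self_mode);

}  // namespace seedoverlap

#endif
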