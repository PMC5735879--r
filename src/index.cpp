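#include <Rcpp.h>
#include "core.h"

using namespace Rcpp;
using namespace seedoverlap;

namespace seedoverlap {

KmerIndex* build_index(const std::vector<std::string>& seqs, int k, int maxc,
                       int minc) {
  KmerIndex* idx = new KmerIndex();
  idx->k = k;
  idx->max_kmer_count = maxc;
  idx->min_kmer_count = minc;
  idx->n_reads = (int)seqs.size();
  for (int rid = 0; rid < (int)seqs.size(); ++rid) {
    CodedRead cr = code_read(seqs[rid]);
    for_each_kmer(cr.fwd, k, [&](uint64_t v, int pos) {
      idx->occ[v].push_back({rid, pos, 0});
      ++idx->n_positions;
    });
    for_each_kmer(cr.rev, k, [&](uint64_t v, int pos) {
      idx->occ[v].push_back({rid, pos, 1});
      ++idx->n_positions;
    });
  }
  // frequency filters on total occurrence counts (both strands summed)
  for (auto it = idx->occ.begin(); it != idx->occ.end();) {
    const std::size_t c = it->second.size();
    if (c > (std::size_t)maxc) {
      ++idx->n_filtered_high;
      it = idx->occ.erase(it);
    } else if (c < (std::size_t)minc) {
      ++idx->n_filtered_low;
      it = idx->occ.erase(it);
    } else {
      ++it;
    }
  }
  return idx;
}

// per-query matches against the index, strand chosen per reference read
// by the larger raw match count (tie -> forward); self mode keeps only
// reference ids strictly greater than qid
std::vector<PairMatches> collect_matches(const KmerIndex& idx,
                                         const std::vector<uint8_t>& qfwd,
                                         int qid, bool self_mode) {
  std::unordered_map<int, std::array<std::vector<Match>, 2>> per_ref;
  for_each_kmer(qfwd, idx.k, [&](uint64_t v, int qpos) {
    auto it = idx.occ.find(v);
    if (it == idx.occ.end()) return;
    for (const Occ& o : it->second) {
      if (self_mode && o.rid <= qid) continue;
      per_ref[o.rid][o.strand].push_back({qpos, o.pos});
    }
  });
  std::vector<PairMatches> out;
  out.reserve(per_ref.size());
  for (auto& kv : per_ref) {
    PairMatches pm;
    pm.ref_id = kv.first;
    pm.strand = kv.second[1].size() > kv.second[0].size() ? 1 : 0;
    pm.V = std::move(kv.second[pm.strand]);
    std::sort(pm.V.begin(), pm.V.end(), [](const Match& a, const Match& b) {
      return a.qpos != b.qpos ? a.qpos < b.qpos : a.rpos < b.rpos;
    });
    pm.V.erase(std::unique(pm.V.begin(), pm.V.end(),
                           [](const Match& a, const Match& b) {
                             return a.qpos == b.qpos && a.rpos == b.rpos;
                           }),
               pm.V.end());
    out.push_back(std::move(pm));
  }
  std::sort(out.begin(), out.end(),
            [](const PairMatches& a, const PairMatches& b) {
              return a.ref_id < b.ref_id;
            });
  return out;
}

}  // namespace seedoverlap

// [[Rcpp::export(name = ".cpp_build_index")]]
SEXP cpp_build_index(std::vector<std::string> seqs, int k, int max_kmer_count,
                     int min_kmer_count) {
  if (k < 1 || k > 32) stop("k must be in [1, 32]");
  XPtr<KmerIndex> ptr(build_index(seqs, k, max_kmer_count, min_kmer_count),
                      true);
  return ptr;
}

// [[Rcpp::export(name = ".cpp_index_stats")]]
List cpp_index_stats(SEXP xp) {
  XPtr<KmerIndex> idx(xp);
  std::size_t entries = 0;
  for (auto& kv : idx->occ) entries += kv.second.size();
  return List::create(
      _["k"] = idx->k, _["n_reads"] = idx->n_reads,
      _["n_kmer_values"] = (double)idx->occ.size(),
      _["n_occurrences"] = (double)entries,
      _["n_positions"] = (double)idx->n_positions,
      _["n_filtered_high"] = (double)idx->n_filtered_high,
      _["n_filtered_low"] = (double)idx->n_filtered_low);
}

// [[Rcpp::export(name = ".cpp_index_lookup")]]
DataFrame cpp_index_lookup(SEXP xp, std::string kmer) {
  XPtr<KmerIndex> idx(xp);
  if ((int)kmer.size() != idx->k) stop("k-mer length must equal index k");
  std::vector<Occ> occ;
  auto it = idx->occ.find(kmer_value(kmer));
  if (it != idx->occ.end()) occ = it->second;
  std::sort(occ.begin(), occ.end(), [](const Occ& a, const Occ& b) {
    if (a.rid != b.rid) return a.rid < b.rid;
    if (a.strand != b.strand) return a.strand < b.strand;
    return a.pos < b.pos;
  });
  IntegerVector rid(occ.size()), pos(occ.size()), strand(occ.size());
  for (std::size_t i = 0; i < occ.size(); ++i) {
    rid[i] = occ[i].rid + 1;  // 1-based read ids on the R side
    pos[i] = occ[i].pos;
    strand[i] = occ[i].strand;
  }
  return DataFrame::create(_["read_id"] = rid, _["pos"] = pos,
                           _["strand"] = strand);
}

// [[Rcpp::export(name = ".cpp_collect_matches")]]
List cpp_collect_matches(SEXP xp, std::string query, int query_id,
                         bool self_mode) {
  XPtr<KmerIndex> idx(xp);
  CodedRead q = code_read(query);
  std::vector<PairMatches> pm =
      collect_matches(*idx, q.fwd, query_id - 1, self_mode);
  List out(pm.size());
  for (std::size_t i = 0; i < pm.size(); ++i) {
    IntegerVector qpos(pm[i].V.size()), rpos(pm[i].V.size());
    for (std::size_t j = 0; j < pm[i].V.size(); ++j) {
      qpos[j] = pm[i].V[j].qpos;
      rpos[j] = pm[i].V[j].rpos;
    }
    out[i] = List::create(
        _["ref_id"] = pm[i].ref_id + 1, _["strand"] = pm[i].strand,
        _["matches"] = DataFrame::create(_["qpos"] = qpos, _["rpos"] = rpos));
  }
  return out;
}
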