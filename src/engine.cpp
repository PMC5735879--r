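#include <Rcpp.h>
#include "core.h"

using namespace Rcpp;
using namespace seedoverlap;

namespace {

std::vector<Match> matches_from_r(IntegerVector qpos, IntegerVector rpos) {
  if (qpos.size() != rpos.size()) stop("qpos and rpos must have equal length");
  std::vector<Match> V(qpos.size());
  for (int i = 0; i < qpos.size(); ++i) V[i] = {qpos[i], rpos[i]};
  return V;
}

PairParams params_from_r(List par) {
  PairParams p;
  p.k = as<int>(par["k"]);
  p.small_k = as<int>(par["small_k"]);
  p.max_shift = as<double>(par["max_shift"]);
  p.error_rate = as<double>(par["error_rate"]);
  p.max_kmer_count = as<int>(par["max_kmer_count"]);
  return p;
}

List result_to_r(const PairResult& r) {
  return List::create(
      _["found"] = r.found, _["reclustered"] = r.reclustered,
      _["cluster_pass"] = r.cluster_pass,
      _["cluster"] = List::create(_["q_l"] = r.q_l, _["r_l"] = r.r_l,
                                  _["q_r"] = r.q_r, _["r_r"] = r.r_r,
                                  _["hits"] = r.cluster_hits,
                                  _["matched_bp"] = r.cluster_bp,
                                  _["threshold"] = r.cluster_threshold),
      _["window"] =
          List::create(_["query_start"] = r.window.query_start,
                       _["query_end"] = r.window.query_end,
                       _["ref_start"] = r.window.ref_start,
                       _["ref_end"] = r.window.ref_end),
      _["q_start"] = r.q_start, _["q_end"] = r.q_end,
      _["r_start"] = r.r_start, _["r_end"] = r.r_end,
      _["total_hits"] = r.total_hits,
      _["final_threshold"] = r.final_threshold, _["score"] = r.score,
      _["identity"] = r.identity);
}

}  // namespace

// [[Rcpp::export(name = ".cpp_cluster_matches")]]
DataFrame cpp_cluster_matches(IntegerVector qpos, IntegerVector rpos, int k,
                              double max_shift) {
  std::vector<Match> V = matches_from_r(qpos, rpos);
  std::vector<Cluster> cl = cluster_matches(V, k, max_shift);
  IntegerVector l(cl.size()), r(cl.size()), bp(cl.size()), h(cl.size());
  for (std::size_t i = 0; i < cl.size(); ++i) {
    l[i] = cl[i].left + 1;  // 1-based indices into V on the R side
    r[i] = cl[i].right + 1;
    bp[i] = cl[i].matched_bp;
    h[i] = cl[i].hits;
  }
  return DataFrame::create(_["left_idx"] = l, _["right_idx"] = r,
                           _["matched_bp"] = bp, _["hit_count"] = h);
}

// [[Rcpp::export(name = ".cpp_binomial_threshold")]]
NumericVector cpp_binomial_threshold(NumericVector L, double e, int k) {
  NumericVector out(L.size());
  for (int i = 0; i < L.size(); ++i) out[i] = binom_threshold(L[i], e, k);
  return out;
}

// [[Rcpp::export(name = ".cpp_max_bounds")]]
List cpp_max_bounds(int q_l, int r_l, int q_r, int r_r, int query_size,
                    int ref_size, double max_shift) {
  MaxBounds b =
      max_bounds(q_l, r_l, q_r, r_r, query_size, ref_size, max_shift);
  return List::create(_["query_start"] = b.query_start,
                      _["query_end"] = b.query_end,
                      _["ref_start"] = b.ref_start,
                      _["ref_end"] = b.ref_end);
}

// [[Rcpp::export(name = ".cpp_pair_overlap")]]
List cpp_pair_overlap(std::string query, std::string ref_oriented,
                      IntegerVector qpos, IntegerVector rpos, List par) {
  CodedRead q = code_read(query);
  CodedRead r = code_read(ref_oriented);
  PairResult res =
      pair_pipeline(q.fwd, r.fwd, matches_from_r(qpos, rpos),
                    params_from_r(par));
  return result_to_r(res);
}

// all-vs-all (or two-set) driver; returns one row per reported overlap,
// reference coordinates flipped to the forward strand
// [[Rcpp::export(name = ".cpp_overlap_all")]]
DataFrame cpp_overlap_all(std::vector<std::string> ref_seqs,
                          std::vector<std::string> query_seqs, bool self_mode,
                          List par, int min_kmer_count, int min_olap_len) {
  PairParams pp = params_from_r(par);
  XPtr<KmerIndex> idx(
      build_index(ref_seqs, pp.k, pp.max_kmer_count, min_kmer_count), true);

  std::vector<CodedRead> refs(ref_seqs.size());
  for (std::size_t i = 0; i < ref_seqs.size(); ++i)
    refs[i] = code_read(ref_seqs[i]);

  std::vector<int> out_q, out_r, out_strand, out_qs, out_qe, out_rs, out_re,
      out_hits, out_score;
  std::vector<double> out_idy;
  std::size_t pairs_examined = 0;

  const std::size_t nq = self_mode ? ref_seqs.size() : query_seqs.size();
  for (std::size_t qi = 0; qi < nq; ++qi) {
    const CodedRead* q;
    CodedRead qtmp;
    if (self_mode) {
      q = &refs[qi];
    } else {
      qtmp = code_read(query_seqs[qi]);
      q = &qtmp;
    }
    if (q->len < pp.k) continue;
    std::vector<PairMatches> pm =
        collect_matches(*idx, q->fwd, (int)qi, self_mode);
    for (PairMatches& m : pm) {
      ++pairs_examined;
      const CodedRead& rref = refs[m.ref_id];
      const std::vector<uint8_t>& rcodes =
          m.strand == 0 ? rref.fwd : rref.rev;
      PairResult res =
          pair_pipeline(q->fwd, rcodes, std::move(m.V), pp);
      if (!res.found) continue;
      int rs = res.r_start, re = res.r_end;
      if (m.strand == 1) {  // flip to forward-strand coordinates
        rs = rref.len - res.r_end;
        re = rref.len - res.r_start;
      }
      if (std::min(res.q_end - res.q_start, re - rs) < min_olap_len)
        continue;
      out_q.push_back((int)qi + 1);
      out_r.push_back(m.ref_id + 1);
      out_strand.push_back(m.strand);
      out_qs.push_back(res.q_start);
      out_qe.push_back(res.q_end);
      out_rs.push_back(rs);
      out_re.push_back(re);
      out_hits.push_back(res.total_hits);
      out_score.push_back(res.score);
      out_idy.push_back(res.identity);
    }
  }
  DataFrame df = DataFrame::create(
      _["query_id"] = out_q, _["ref_id"] = out_r, _["strand"] = out_strand,
      _["q_start"] = out_qs, _["q_end"] = out_qe, _["r_start"] = out_rs,
      _["r_end"] = out_re, _["total_hits"] = out_hits,
      _["score"] = out_score, _["identity"] = out_idy);
  df.attr("pairs_examined") = (double)pairs_examined;
  return df;
}
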