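#include "core.h"

namespace seedoverlap {

std::vector<Cluster> cluster_matches(const std::vector<Match>& V, int k,
                                     double max_shift) {
  std::vector<Cluster> out;
  const int n = (int)V.size();
  if (n == 0) return out;
  int start = 0;
  auto close = [&](int last) {
    Cluster c;
    c.left = start;
    c.right = last;
    c.hits = last - start + 1;
    // union of [qpos, qpos+k) on the query; qpos non-decreasing within a run
    int bp = 0, cov_end = -1;
    for (int i = start; i <= last; ++i) {
      const int b = V[i].qpos, e = V[i].qpos + k;
      if (b >= cov_end) {
        bp += e - b;
      } else if (e > cov_end) {
        bp += e - cov_end;
      }
      if (e > cov_end) cov_end = e;
    }
    c.matched_bp = bp;
    out.push_back(c);
  };
  for (int i = 1; i < n; ++i) {
    if (!consistent(V[i - 1], V[i], max_shift)) {
      close(i - 1);
      start = i;
    }
  }
  close(n - 1);
  return out;
}

MaxBounds max_bounds(int q_l, int r_l, int q_r, int r_r, int qlen, int rlen,
                     double max_shift) {
  const double f = 1.0 + max_shift;
  auto clampi = [](double x, int lo, int hi) {
    if (x < lo) return lo;
    if (x > hi) return hi;
    return (int)x;
  };
  MaxBounds b;
  b.query_start = clampi(std::floor(q_l - f * r_l), 0, qlen);
  b.ref_start = clampi(std::floor(r_l - f * q_l), 0, rlen);
  b.query_end = clampi(std::ceil(q_r + f * (rlen - r_r)), 0, qlen);
  b.ref_end = clampi(std::ceil(r_r + f * (qlen - q_r)), 0, rlen);
  return b;
}

namespace {

// cluster seed bounds: leftmost k-mer starts and rightmost k-mer ends
struct SeedBounds {
  int q_l, r_l, q_r, r_r;
};

SeedBounds seed_bounds(const std::vector<Match>& V, const Cluster& c, int k) {
  SeedBounds b{V[c.left].qpos, V[c.left].rpos, V[c.left].qpos + k,
               V[c.left].rpos + k};
  for (int i = c.left; i <= c.right; ++i) {
    b.q_l = std::min(b.q_l, V[i].qpos);
    b.r_l = std::min(b.r_l, V[i].rpos);
    b.q_r = std::max(b.q_r, V[i].qpos + k);
    b.r_r = std::max(b.r_r, V[i].rpos + k);
  }
  return b;
}

// best cluster: max matched bp, then max hits, then leftmost on the query
int best_cluster(const std::vector<Match>& V, const std::vector<Cluster>& cl) {
  int best = 0;
  for (int i = 1; i < (int)cl.size(); ++i) {
    const Cluster &a = cl[best], &b = cl[i];
    if (b.matched_bp > a.matched_bp ||
        (b.matched_bp == a.matched_bp &&
         (b.hits > a.hits ||
          (b.hits == a.hits && V[b.left].qpos < V[a.left].qpos))))
      best = i;
  }
  return best;
}

// k'-mer matches between the bounded substrings, absolute coordinates,
// sorted by (qpos, rpos); the occurrence ceiling is applied to the local
// reference-window counts
std::vector<Match> small_kmer_matches(const std::vector<uint8_t>& q,
                                      const std::vector<uint8_t>& r,
                                      const MaxBounds& w,
                                      const PairParams& par) {
  std::vector<Match> out;
  const int kp = par.small_k;
  if (w.ref_end - w.ref_start < kp || w.query_end - w.query_start < kp)
    return out;
  const uint64_t mask = (1ULL << (2 * kp)) - 1ULL;
  std::unordered_map<uint64_t, std::vector<int32_t>> map;
  map.reserve((std::size_t)(w.ref_end - w.ref_start));
  uint64_t val = 0;
  for (int i = w.ref_start; i < w.ref_end; ++i) {
    val = ((val << 2) | r[i]) & mask;
    if (i - w.ref_start >= kp - 1) map[val].push_back(i - kp + 1);
  }
  val = 0;
  for (int i = w.query_start; i < w.query_end; ++i) {
    val = ((val << 2) | q[i]) & mask;
    if (i - w.query_start < kp - 1) continue;
    auto it = map.find(val);
    if (it == map.end()) continue;
    if ((int)it->second.size() > par.max_kmer_count) continue;
    for (int32_t rp : it->second) out.push_back({i - kp + 1, rp});
  }
  std::sort(out.begin(), out.end(), [](const Match& a, const Match& b) {
    return a.qpos != b.qpos ? a.qpos < b.qpos : a.rpos < b.rpos;
  });
  return out;
}

}  // namespace

PairResult pair_pipeline(const std::vector<uint8_t>& q,
                         const std::vector<uint8_t>& r, std::vector<Match> V,
                         const PairParams& par) {
  PairResult res;
  const int qlen = (int)q.size(), rlen = (int)r.size();
  if (V.empty()) return res;

  auto by_q = [](const Match& a, const Match& b) {
    return a.qpos != b.qpos ? a.qpos < b.qpos : a.rpos < b.rpos;
  };
  auto by_r = [](const Match& a, const Match& b) {
    return a.rpos != b.rpos ? a.rpos < b.rpos : a.qpos < b.qpos;
  };
  std::sort(V.begin(), V.end(), by_q);
  V.erase(std::unique(V.begin(), V.end(),
                      [](const Match& a, const Match& b) {
                        return a.qpos == b.qpos && a.rpos == b.rpos;
                      }),
          V.end());

  // pass 1: query-major sort; pass 2 (on failure): reference-major sort
  SeedBounds sb{0, 0, 0, 0};
  Cluster chosen{0, 0, 0, 0};
  bool pass = false;
  for (int attempt = 0; attempt < 2 && !pass; ++attempt) {
    if (attempt == 1) {
      std::sort(V.begin(), V.end(), by_r);
      res.reclustered = true;
    }
    std::vector<Cluster> cl = cluster_matches(V, par.k, par.max_shift);
    if (cl.empty()) continue;
    const int bi = best_cluster(V, cl);
    const SeedBounds b = seed_bounds(V, cl[bi], par.k);
    const double L = align_length(b.q_l, b.q_r, b.r_l, b.r_r, qlen, rlen);
    const double thr = binom_threshold(L, par.error_rate, par.k);
    res.q_l = b.q_l;
    res.r_l = b.r_l;
    res.q_r = b.q_r;
    res.r_r = b.r_r;
    res.cluster_hits = cl[bi].hits;
    res.cluster_bp = cl[bi].matched_bp;
    res.cluster_threshold = thr;
    if ((double)cl[bi].hits >= thr) {
      pass = true;
      sb = b;
      chosen = cl[bi];
    }
  }
  res.cluster_pass = pass;
  if (!pass) return res;

  // extension window and k'-mer matches inside it
  const MaxBounds w =
      max_bounds(sb.q_l, sb.r_l, sb.q_r, sb.r_r, qlen, rlen, par.max_shift);
  res.window = w;
  const std::vector<Match> S = small_kmer_matches(q, r, w, par);
  const int kp = par.small_k;

  int q_start = sb.q_l, r_start = sb.r_l, q_end = sb.q_r, r_end = sb.r_r;
  std::vector<Match> accepted;  // k'-mers accepted during extension

  // leftward: candidates in order of decreasing qpos below the cluster;
  // drift-inconsistent candidates are skipped, the mu-3sigma failure stops
  {
    int aq = sb.q_l, ar = sb.r_l, h = 0;
    for (int i = (int)S.size() - 1; i >= 0; --i) {
      const Match& m = S[i];
      if (m.qpos >= sb.q_l) continue;
      if (m.qpos >= aq || m.rpos >= ar) continue;
      const int dq = aq - m.qpos, dr = ar - m.rpos;
      const int diff = dq > dr ? dq - dr : dr - dq;
      if ((double)diff > par.max_shift * (double)std::max(dq, dr)) continue;
      const double L =
          std::max((double)(sb.q_l - m.qpos), (double)(sb.r_l - m.rpos)) + kp;
      if ((double)(h + 1) < binom_threshold(L, par.error_rate, kp)) break;
      ++h;
      aq = m.qpos;
      ar = m.rpos;
      q_start = m.qpos;
      r_start = m.rpos;
      accepted.push_back(m);
    }
  }
  // rightward: candidates in order of increasing end beyond the cluster
  {
    int aqe = sb.q_r, are = sb.r_r, h = 0;
    for (int i = 0; i < (int)S.size(); ++i) {
      const Match& m = S[i];
      const int qe = m.qpos + kp, re = m.rpos + kp;
      if (qe <= sb.q_r) continue;
      if (qe <= aqe || re <= are) continue;
      const int dq = qe - aqe, dr = re - are;
      const int diff = dq > dr ? dq - dr : dr - dq;
      if ((double)diff > par.max_shift * (double)std::max(dq, dr)) continue;
      const double L =
          std::max((double)(qe - sb.q_r), (double)(re - sb.r_r)) + kp;
      if ((double)(h + 1) < binom_threshold(L, par.error_rate, kp)) break;
      ++h;
      aqe = qe;
      are = re;
      q_end = qe;
      r_end = re;
      accepted.push_back(m);
    }
  }

  // final validation: all k'-mer matches inside the final region, against
  // the mu-3sigma floor at p = (1-e)^(2k')
  int hits = 0;
  for (const Match& m : S)
    if (m.qpos >= q_start && m.qpos + kp <= q_end && m.rpos >= r_start &&
        m.rpos + kp <= r_end)
      ++hits;
  const double Lf =
      std::max((double)(q_end - q_start), (double)(r_end - r_start));
  const double thr = binom_threshold(Lf, par.error_rate, kp);
  res.q_start = q_start;
  res.q_end = q_end;
  res.r_start = r_start;
  res.r_end = r_end;
  res.total_hits = hits;
  res.final_threshold = thr;
  if ((double)hits < thr) return res;

  // matched bp: union on the query of cluster k-mers and accepted k'-mers
  std::vector<std::pair<int, int>> iv;
  for (int i = chosen.left; i <= chosen.right; ++i)
    iv.push_back({V[i].qpos, V[i].qpos + par.k});
  for (const Match& m : accepted) iv.push_back({m.qpos, m.qpos + kp});
  std::sort(iv.begin(), iv.end());
  int bp = 0, cov = -1;
  for (auto& p : iv) {
    if (p.first >= cov)
      bp += p.second - p.first;
    else if (p.second > cov)
      bp += p.second - cov;
    if (p.second > cov) cov = p.second;
  }
  res.score = bp;
  // identity from observed seed density through the survival law
  const double f =
      std::min(1.0, (double)hits / std::max(1.0, Lf));
  res.identity = f <= 0.0 ? 0.0 : std::pow(f, 1.0 / (2.0 * kp));
  res.found = true;
  return res;
}

}  // namespace seedoverlap
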