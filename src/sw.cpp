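#include <Rcpp.h>
#include "core.h"

using namespace Rcpp;
using namespace seedoverlap;

namespace {

struct ScoreHit {
  int score = 0;
  int i = 0, j = 0;  // 1-based end coordinates (exclusive 0-based ends)
};

// score-only local alignment pass, linear gap penalty; first maximum in
// row-major order -> smallest end coordinates at ties
ScoreHit score_pass(const std::string& a, const std::string& b, int match,
                    int mismatch, int gap) {
  const int n = (int)a.size(), m = (int)b.size();
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  ScoreHit best;
  for (int i = 1; i <= n; ++i) {
    cur[0] = 0;
    const char ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      const int diag = prev[j - 1] + (ai == b[j - 1] ? match : mismatch);
      const int up = prev[j] + gap;
      const int left = cur[j - 1] + gap;
      int v = diag;
      if (up > v) v = up;
      if (left > v) v = left;
      if (v < 0) v = 0;
      cur[j] = v;
      if (v > best.score) {
        best.score = v;
        best.i = i;
        best.j = j;
      }
    }
    std::swap(prev, cur);
  }
  return best;
}

struct TraceStats {
  int matches = 0, columns = 0, gaps = 0;
  int a_start = 0, b_start = 0;  // 0-based
};

// full traceback on a (small) sub-rectangle; returns the alignment ending
// at the best cell, which equals the global optimum when the rectangle is
// the span of an optimal alignment
TraceStats trace_pass(const std::string& a, const std::string& b, int match,
                      int mismatch, int gap) {
  const int n = (int)a.size(), m = (int)b.size();
  std::vector<uint8_t> tb((std::size_t)n * m, 0);  // 0 stop, 1 diag, 2 up, 3 left
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  ScoreHit best;
  for (int i = 1; i <= n; ++i) {
    cur[0] = 0;
    const char ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      const int diag = prev[j - 1] + (ai == b[j - 1] ? match : mismatch);
      const int up = prev[j] + gap;
      const int left = cur[j - 1] + gap;
      int v = diag;
      uint8_t dir = 1;
      if (up > v) { v = up; dir = 2; }
      if (left > v) { v = left; dir = 3; }
      if (v <= 0) { v = v < 0 ? 0 : v; if (v == 0) dir = 0; }
      cur[j] = v;
      tb[(std::size_t)(i - 1) * m + (j - 1)] = dir;
      if (v > best.score) {
        best.score = v;
        best.i = i;
        best.j = j;
      }
    }
    std::swap(prev, cur);
  }
  TraceStats st;
  int i = best.i, j = best.j;
  while (i > 0 && j > 0) {
    const uint8_t dir = tb[(std::size_t)(i - 1) * m + (j - 1)];
    if (dir == 0) break;
    ++st.columns;
    if (dir == 1) {
      if (a[i - 1] == b[j - 1]) ++st.matches;
      --i;
      --j;
    } else if (dir == 2) {
      ++st.gaps;
      --i;
    } else {
      ++st.gaps;
      --j;
    }
  }
  st.a_start = i;
  st.b_start = j;
  return st;
}

}  // namespace

namespace {

List empty_alignment() {
  return List::create(_["score"] = 0, _["a_start"] = 0, _["a_end"] = 0,
                      _["b_start"] = 0, _["b_end"] = 0, _["matches"] = 0,
                      _["columns"] = 0, _["gaps"] = 0,
                      _["identity"] = NA_REAL);
}

// complete an alignment whose end cell (1-based i, j) is already known:
// reversed score pass locates the start, traceback over the optimal span
// collects the column statistics
List finish_from_end(const std::string& a, const std::string& b,
                     const ScoreHit& end, int match, int mismatch, int gap) {
  std::string ra(a.rbegin() + (a.size() - end.i), a.rend());
  std::string rb(b.rbegin() + (b.size() - end.j), b.rend());
  ScoreHit start = score_pass(ra, rb, match, mismatch, gap);
  const int a_start = end.i - start.i, b_start = end.j - start.j;
  std::string sa = a.substr(a_start, end.i - a_start);
  std::string sb = b.substr(b_start, end.j - b_start);
  TraceStats st = trace_pass(sa, sb, match, mismatch, gap);
  return List::create(
      _["score"] = end.score, _["a_start"] = a_start + st.a_start,
      _["a_end"] = end.i, _["b_start"] = b_start + st.b_start,
      _["b_end"] = end.j, _["matches"] = st.matches,
      _["columns"] = st.columns, _["gaps"] = st.gaps,
      _["identity"] =
          st.columns > 0 ? (double)st.matches / st.columns : NA_REAL);
}

}  // namespace

// score-only pass: optimal local score and its end coordinates (first
// maximum in row-major order)
// [[Rcpp::export(name = ".cpp_sw_score")]]
List cpp_sw_score(std::string a, std::string b, int match, int mismatch,
                  int gap) {
  if (a.empty() || b.empty()) stop("sequences must be non-empty");
  ScoreHit end = score_pass(a, b, match, mismatch, gap);
  return List::create(_["score"] = end.score, _["a_end"] = end.i,
                      _["b_end"] = end.j);
}

// complete a local alignment from a known end cell (exclusive 0-based
// coordinates a_end, b_end) without repeating the forward pass
// [[Rcpp::export(name = ".cpp_sw_finish")]]
List cpp_sw_finish(std::string a, std::string b, int score, int a_end,
                   int b_end, int match, int mismatch, int gap) {
  if (score <= 0) return empty_alignment();
  ScoreHit end;
  end.score = score;
  end.i = a_end;
  end.j = b_end;
  return finish_from_end(a, b, end, match, mismatch, gap);
}

// optimal local alignment: score pass for the end, reversed score pass for
// the start, traceback restricted to the optimal span (keeps memory linear
// in the read lengths except for the aligned region itself)
// [[Rcpp::export(name = ".cpp_smith_waterman")]]
List cpp_smith_waterman(std::string a, std::string b, int match, int mismatch,
                        int gap) {
  if (a.empty() || b.empty()) stop("sequences must be non-empty");
  ScoreHit end = score_pass(a, b, match, mismatch, gap);
  if (end.score <= 0) return empty_alignment();
  return finish_from_end(a, b, end, match, mismatch, gap);
}
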