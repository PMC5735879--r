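#include <Rcpp.h>
#include "core.h"

using namespace Rcpp;
using namespace seedoverlap;

// 2-bit packing: base j occupies bits 2*(j%4) .. 2*(j%4)+1 of byte j/4

// [[Rcpp::export(name = ".cpp_encode_2bit")]]
RawVector cpp_encode_2bit(std::string seq) {
  const int n = (int)seq.size();
  RawVector out((n + 3) / 4);
  int replaced = 0;
  for (int i = 0; i < n; ++i) {
    int c = base_code(seq[i]);
    if (c < 0) { c = 0; ++replaced; }
    out[i >> 2] |= (Rbyte)(c << ((i & 3) << 1));
  }
  out.attr("n_bases") = n;
  out.attr("n_replaced") = replaced;
  return out;
}

// [[Rcpp::export(name = ".cpp_decode_2bit")]]
std::string cpp_decode_2bit(RawVector code, int length) {
  if (length < 0 || length > 4 * code.size())
    stop("length exceeds the number of stored bases");
  std::string out(length, 'A');
  for (int i = 0; i < length; ++i)
    out[i] = code_base((code[i >> 2] >> ((i & 3) << 1)) & 3);
  return out;
}

// [[Rcpp::export(name = ".cpp_revcomp")]]
std::string cpp_revcomp(std::string seq) {
  const int n = (int)seq.size();
  std::string out(n, 'A');
  for (int i = 0; i < n; ++i) {
    int c = base_code(seq[n - 1 - i]);
    out[i] = code_base(c < 0 ? 3 : 3 - c);
  }
  return out;
}
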