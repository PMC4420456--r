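#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Plain Levenshtein distance, unit cost for insertion, deletion, substitution.
// Two-row dynamic programme; strings are compared byte-wise (inputs are
// normalised to lower-case ASCII upstream).
static int lev(const std::string& a, const std::string& b) {
  const size_t n = a.size(), m = b.size();
  if (n == 0) return (int)m;
  if (m == 0) return (int)n;
  std::vector<int> prev(m + 1), cur(m + 1);
  for (size_t j = 0; j <= m; ++j) prev[j] = (int)j;
  for (size_t i = 1; i <= n; ++i) {
    cur[0] = (int)i;
    for (size_t j = 1; j <= m; ++j) {
      int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      cur[j] = std::min(sub, std::min(prev[j] + 1, cur[j - 1] + 1));
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// [[Rcpp::export]]
IntegerVector levenshtein_cpp(CharacterVector a, CharacterVector b) {
  R_xlen_t n = a.size();
  if (b.size() != n) stop("internal: levenshtein_cpp inputs must have equal length");
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (CharacterVector::is_na(a[i]) || CharacterVector::is_na(b[i])) {
      out[i] = NA_INTEGER;
    } else {
      out[i] = lev(as<std::string>(a[i]), as<std::string>(b[i]));
    }
  }
  return out;
}
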