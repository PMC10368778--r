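#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Classic Wagner–Fischer dynamic programme, two rolling rows.
// sub_cost = 1 gives the plain Levenshtein distance (insertions,
// omissions, substitutions all cost 1). sub_cost = 2 prices a
// substitution as a deletion plus an insertion, the convention some
// library ratio() functions use.
static int lev_one(const std::string &a, const std::string &b,
                   const int sub_cost) {
  const size_t n = a.size(), m = b.size();
  if (n == 0) return static_cast<int>(m);
  if (m == 0) return static_cast<int>(n);
  std::vector<int> prev(m + 1), cur(m + 1);
  for (size_t j = 0; j <= m; ++j) prev[j] = static_cast<int>(j);
  for (size_t i = 1; i <= n; ++i) {
    cur[0] = static_cast<int>(i);
    for (size_t j = 1; j <= m; ++j) {
      const int del = prev[j] + 1;
      const int ins = cur[j - 1] + 1;
      const int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : sub_cost);
      cur[j] = std::min(del, std::min(ins, sub));
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// [[Rcpp::export]]
IntegerVector lev_distance_cpp(CharacterVector a, CharacterVector b,
                               int sub_cost = 1) {
  const R_xlen_t na = a.size(), nb = b.size();
  const R_xlen_t n = std::max(na, nb);
  if (na == 0 || nb == 0) return IntegerVector(0);
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (CharacterVector::is_na(a[i % na]) ||
        CharacterVector::is_na(b[i % nb])) {
      out[i] = NA_INTEGER;
      continue;
    }
    const std::string sa = as<std::string>(a[i % na]);
    const std::string sb = as<std::string>(b[i % nb]);
    out[i] = lev_one(sa, sb, sub_cost);
  }
  return out;
}
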