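#include <Rcpp.h>
using namespace Rcpp;

// Unit-cost global alignment (Levenshtein) distance between two normalized
// DNA strings. 'N' matches any base at zero cost; indels always cost 1.
static int lev_wild(const std::string& a, const std::string& b) {
  const int n = a.size(), m = b.size();
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    const char ca = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      const char cb = b[j - 1];
      const int sub = (ca == cb || ca == 'N' || cb == 'N') ? 0 : 1;
      int best = prev[j - 1] + sub;
      if (prev[j] + 1 < best) best = prev[j] + 1;
      if (cur[j - 1] + 1 < best) best = cur[j - 1] + 1;
      cur[j] = best;
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// [[Rcpp::export(name = ".edit_distance_cpp")]]
int edit_distance_cpp(std::string a, std::string b) {
  return lev_wild(a, b);
}

// [[Rcpp::export(name = ".edit_distance_matrix_cpp")]]
IntegerMatrix edit_distance_matrix_cpp(CharacterVector seqs) {
  const int n = seqs.size();
  IntegerMatrix d(n, n);
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<std::string>(seqs[i]);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const int v = lev_wild(s[i], s[j]);
      d(i, j) = v;
      d(j, i) = v;
    }
  }
  return d;
}
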