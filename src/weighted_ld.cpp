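#include <Rcpp.h>
using namespace Rcpp;

// Weighted Levenshtein distance between two label sequences given as
// 1-based indices into the rows/columns of a substitution-cost matrix.
// Insertions and deletions cost `indel`; substitutions cost `costs(a, b)`
// (0 on the diagonal). Full (|a|+1) x (|b|+1) dynamic-programming table:
// strings are short (tens of units), no banding needed.
// [[Rcpp::export(name = ".weighted_ld_cpp")]]
double weighted_ld_cpp(IntegerVector a, IntegerVector b,
                       NumericMatrix costs, double indel) {
  const int n = a.size(), m = b.size();
  std::vector<double> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j * indel;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i * indel;
    const int ai = a[i - 1] - 1;
    for (int j = 1; j <= m; ++j) {
      const int bj = b[j - 1] - 1;
      double sub = prev[j - 1] + costs(ai, bj);
      double del = prev[j] + indel;
      double ins = cur[j - 1] + indel;
      cur[j] = std::min(sub, std::min(del, ins));
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// All pairwise weighted Levenshtein distances among a list of index
// sequences; returns the symmetric n x n matrix.
// [[Rcpp::export(name = ".pairwise_ld_cpp")]]
NumericMatrix pairwise_ld_cpp(List seqs, NumericMatrix costs, double indel) {
  const int n = seqs.size();
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    IntegerVector si = seqs[i];
    for (int j = i + 1; j < n; ++j) {
      IntegerVector sj = seqs[j];
      double d = weighted_ld_cpp(si, sj, costs, indel);
      out(i, j) = d;
      out(j, i) = d;
    }
  }
  return out;
}
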