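#include <Rcpp.h>

using namespace Rcpp;

// Iterative two-row DP; O(|a|*|b|) time, O(min) space would need swap logic,
// plain two full rows is fine at KE-label scale.
static int lev_one(const char *a, int m, const char *b, int n) {
  std::vector<int> prev(n + 1), cur(n + 1);
  for (int j = 0; j <= n; ++j) prev[j] = j;
  for (int i = 1; i <= m; ++i) {
    cur[0] = i;
    for (int j = 1; j <= n; ++j) {
      int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      int del = prev[j] + 1;
      int ins = cur[j - 1] + 1;
      cur[j] = std::min(sub, std::min(del, ins));
    }
    std::swap(prev, cur);
  }
  return prev[n];
}

// [[Rcpp::export]]
IntegerVector lev_dist_cpp(CharacterVector a, CharacterVector b) {
  R_xlen_t n = std::max(a.size(), b.size());
  if (a.size() != b.size() && a.size() != 1 && b.size() != 1)
    stop("arguments must have equal length or length one");
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    SEXP sa = a[a.size() == 1 ? 0 : i];
    SEXP sb = b[b.size() == 1 ? 0 : i];
    if (sa == NA_STRING || sb == NA_STRING) { out[i] = NA_INTEGER; continue; }
    const char *ca = CHAR(sa);
    const char *cb = CHAR(sb);
    out[i] = lev_one(ca, (int) strlen(ca), cb, (int) strlen(cb));
  }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix lev_matrix_cpp(CharacterVector x, CharacterVector y) {
  R_xlen_t nx = x.size(), ny = y.size();
  IntegerMatrix out(nx, ny);
  for (R_xlen_t i = 0; i < nx; ++i) {
    if (x[i] == NA_STRING) { for (R_xlen_t j = 0; j < ny; ++j) out(i, j) = NA_INTEGER; continue; }
    const char *ca = CHAR(STRING_ELT(x, i));
    int m = (int) strlen(ca);
    for (R_xlen_t j = 0; j < ny; ++j) {
      if (y[j] == NA_STRING) { out(i, j) = NA_INTEGER; continue; }
      const char *cb = CHAR(STRING_ELT(y, j));
      out(i, j) = lev_one(ca, m, cb, (int) strlen(cb));
    }
  }
  return out;
}
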