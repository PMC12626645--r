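#include <Rcpp.h>
using namespace Rcpp;

// Between-community mean nearest taxon distance.
// comm: n_samples x n_taxa weights (relative abundances, or 1/richness for the
// unweighted variant); zero means absent. d: n_taxa x n_taxa patristic
// distances, rows/cols aligned with comm columns.
// [[Rcpp::export]]
NumericMatrix bmntd_cpp(NumericMatrix comm, NumericMatrix d) {
  const int n = comm.nrow();
  const int s = comm.ncol();
  if (d.nrow() != s || d.ncol() != s)
    stop("distance matrix does not match the taxon set");

  std::vector<std::vector<int>> present(n);
  for (int k = 0; k < n; ++k)
    for (int i = 0; i < s; ++i)
      if (comm(k, i) > 0.0) present[k].push_back(i);

  NumericMatrix out(n, n);
  for (int k = 0; k < n; ++k) {
    for (int l = k + 1; l < n; ++l) {
      double acc = 0.0;
      // direction k -> l
      for (int ii : present[k]) {
        double dmin = R_PosInf;
        for (int jj : present[l]) {
          double v = d(ii, jj);
          if (v < dmin) dmin = v;
        }
        acc += 0.5 * comm(k, ii) * dmin;
      }
      // direction l -> k
      for (int jj : present[l]) {
        double dmin = R_PosInf;
        for (int ii : present[k]) {
          double v = d(jj, ii);
          if (v < dmin) dmin = v;
        }
        acc += 0.5 * comm(l, jj) * dmin;
      }
      out(k, l) = acc;
      out(l, k) = acc;
    }
  }
  return out;
}

// Null distribution helper: betaMNTD for each tip-label permutation.
// perms: n_null x n_taxa matrix of 1-based taxon index permutations.
// Returns n_null x n_pairs matrix, pairs in column-major (k < l) order.
// [[Rcpp::export]]
NumericMatrix bmntd_null_cpp(NumericMatrix comm, NumericMatrix d,
                             IntegerMatrix perms) {
  const int n = comm.nrow();
  const int s = comm.ncol();
  const int n_null = perms.nrow();
  const int n_pairs = n * (n - 1) / 2;
  if (perms.ncol() != s) stop("permutation width does not match taxon count");

  std::vector<std::vector<int>> present(n);
  for (int k = 0; k < n; ++k)
    for (int i = 0; i < s; ++i)
      if (comm(k, i) > 0.0) present[k].push_back(i);

  NumericMatrix out(n_null, n_pairs);
  for (int r = 0; r < n_null; ++r) {
    std::vector<int> p(s);
    for (int i = 0; i < s; ++i) {
      int v = perms(r, i);
      if (v < 1 || v > s) stop("permutation index out of range");
      p[i] = v - 1;
    }
    int col = 0;
    for (int k = 0; k < n; ++k) {
      for (int l = k + 1; l < n; ++l) {
        double acc = 0.0;
        for (int ii : present[k]) {
          double dmin = R_PosInf;
          for (int jj : present[l]) {
            double v = d(p[ii], p[jj]);
            if (v < dmin) dmin = v;
          }
          acc += 0.5 * comm(k, ii) * dmin;
        }
        for (int jj : present[l]) {
          double dmin = R_PosInf;
          for (int ii : present[k]) {
            double v = d(p[jj], p[ii]);
            if (v < dmin) dmin = v;
          }
          acc += 0.5 * comm(l, jj) * dmin;
        }
        out(r, col++) = acc;
      }
    }
    if ((r & 31) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
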