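#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Two-pointer merge over sorted bin indices: cost is linear in the number of
// occupied bins of the two sparse vectors.

// [[Rcpp::export]]
double sparse_dot_cpp(IntegerVector ia, NumericVector va,
                      IntegerVector ib, NumericVector vb) {
  R_xlen_t i = 0, j = 0, na = ia.size(), nb = ib.size();
  double acc = 0.0;
  while (i < na && j < nb) {
    if (ia[i] < ib[j]) {
      ++i;
    } else if (ia[i] > ib[j]) {
      ++j;
    } else {
      acc += va[i] * vb[j];
      ++i;
      ++j;
    }
  }
  return acc;
}

// Euclidean norm of the element-wise sum of two sparse vectors, computed on
// the merged support (shared bins add before squaring).

// [[Rcpp::export]]
double merged_norm_cpp(IntegerVector ia, NumericVector va,
                       IntegerVector ib, NumericVector vb) {
  R_xlen_t i = 0, j = 0, na = ia.size(), nb = ib.size();
  double acc = 0.0;
  while (i < na && j < nb) {
    if (ia[i] < ib[j]) {
      acc += va[i] * va[i];
      ++i;
    } else if (ia[i] > ib[j]) {
      acc += vb[j] * vb[j];
      ++j;
    } else {
      double s = va[i] + vb[j];
      acc += s * s;
      ++i;
      ++j;
    }
  }
  for (; i < na; ++i) acc += va[i] * va[i];
  for (; j < nb; ++j) acc += vb[j] * vb[j];
  return std::sqrt(acc);
}
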