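#include <Rcpp.h>
using namespace Rcpp;

// sin(x)/x with a series branch near 0; the diagonal of the Debye matrix
// hits x = 0 exactly and must evaluate to the limit 1.
static inline double sinc(double x) {
  if (std::fabs(x) < 1e-6) return 1.0 - x * x / 6.0;
  return std::sin(x) / x;
}

// Debye cross sum: S(q) = sum_i sum_j A_i(q) * B_j(q) * sinc(q * r_ij)
// coords: N x 3 (Angstrom); fa, fb: nq x N per-atom factors; q: nq grid.
// With fa == fb this is the exact Debye intensity; with two different
// factor sets it is one cross term of the quadratic (c1, c2) decomposition.
// [[Rcpp::export]]
NumericVector debye_cross_cpp(NumericMatrix coords, NumericMatrix fa,
                              NumericMatrix fb, NumericVector q) {
  const int n = coords.nrow(), nq = q.size();
  NumericVector out(nq);
  // diagonal (r_ij = 0, sinc = 1)
  for (int k = 0; k < nq; ++k) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += fa(k, i) * fb(k, i);
    out[k] = s;
  }
  // off-diagonal pairs, symmetrised so the full double sum is reproduced
  for (int i = 0; i < n; ++i) {
    const double xi = coords(i, 0), yi = coords(i, 1), zi = coords(i, 2);
    for (int j = i + 1; j < n; ++j) {
      const double dx = xi - coords(j, 0), dy = yi - coords(j, 1),
                   dz = zi - coords(j, 2);
      const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      for (int k = 0; k < nq; ++k) {
        const double s = sinc(q[k] * r);
        out[k] += (fa(k, i) * fb(k, j) + fa(k, j) * fb(k, i)) * s;
      }
    }
  }
  return out;
}

// Row partial sums of the Debye matrix: for each requested row i,
// I_partial,i(q) = sum_j F_i(q) F_j(q) sinc(q r_ij) over ALL columns j.
// Summing the returned columns over a disjoint cover of rows 1..N
// reproduces the full double sum. rows is 1-based.
// [[Rcpp::export]]
NumericMatrix debye_rows_cpp(NumericMatrix coords, NumericMatrix fq,
                             NumericVector q, IntegerVector rows) {
  const int n = coords.nrow(), nq = q.size(), nr = rows.size();
  NumericMatrix out(nq, nr);
  for (int ri = 0; ri < nr; ++ri) {
    const int i = rows[ri] - 1;
    if (i < 0 || i >= n) stop("row index out of range");
    const double xi = coords(i, 0), yi = coords(i, 1), zi = coords(i, 2);
    for (int j = 0; j < n; ++j) {
      const double dx = xi - coords(j, 0), dy = yi - coords(j, 1),
                   dz = zi - coords(j, 2);
      const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      for (int k = 0; k < nq; ++k)
        out(k, ri) += fq(k, i) * fq(k, j) * sinc(q[k] * r);
    }
  }
  return out;
}

// All N(N-1)/2 pairwise distances, row-major over i < j.
// [[Rcpp::export]]
NumericVector pair_distances_cpp(NumericMatrix coords) {
  const int n = coords.nrow();
  const R_xlen_t np = (R_xlen_t)n * (n - 1) / 2;
  NumericVector out(np);
  R_xlen_t k = 0;
  for (int i = 0; i < n; ++i) {
    const double xi = coords(i, 0), yi = coords(i, 1), zi = coords(i, 2);
    for (int j = i + 1; j < n; ++j) {
      const double dx = xi - coords(j, 0), dy = yi - coords(j, 1),
                   dz = zi - coords(j, 2);
      out[k++] = std::sqrt(dx * dx + dy * dy + dz * dz);
    }
  }
  return out;
}
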