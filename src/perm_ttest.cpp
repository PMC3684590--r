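#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Pooled-variance two-sample t^2 for one edge given the patient-group sum and
// sum of squares. Degenerate pooled variance: returns NaN when the mean
// difference is also ~0 (undefined t), +Inf otherwise (infinite separation).
static inline double t2_stat(double s1, double q1, double tot, double totsq,
                             double n1, double n2, double df, double invn,
                             double tiny) {
  double s2 = tot - s1;
  double diff = s1 / n1 - s2 / n2;
  double ss = totsq - s1 * s1 / n1 - s2 * s2 / n2;  // within-group SS
  double denom = (ss / df) * invn;
  if (!(denom > tiny)) {
    if (diff * diff <= tiny) return NA_REAL;
    return R_PosInf;
  }
  return diff * diff / denom;
}

// Fold-batched permutation t-test ranks.
//
// X:        n x E subject-by-edge matrix.
// patient:  length-n 0/1 observed patient indicator.
// include:  F x n 0/1 matrix; row f marks the subjects a fold trains on.
// P:        B x n 0/1 matrix of permuted patient assignments; each row
//           assigns within one fold's included subjects only and preserves
//           that fold's group sizes.
// fold:     length-B 1-based fold id of each permutation row.
//
// Returns, per fold f and edge e, the observed pooled-variance t^2 on the
// included subjects and the number of that fold's permutation rows whose
// t^2 is at least as large. Because the fold's total sum and sum of squares
// are invariant under label permutation, t^2 is a monotone function of the
// squared group-mean difference, itself affine in the permuted patient sum:
// the rank comparison therefore needs only the single product P * X.
// Columns are processed in blocks so the B x E intermediate never
// materializes.
// [[Rcpp::export(name = ".perm_ttest_counts")]]
List perm_ttest_counts(const arma::mat& X, const arma::vec& patient,
                       const arma::mat& include, const arma::mat& P,
                       const arma::ivec& fold, int block = 1024) {
  const arma::uword n = X.n_rows, E = X.n_cols;
  const arma::uword F = include.n_rows, B = P.n_rows;
  if (patient.n_elem != n || include.n_cols != n || P.n_cols != n ||
      fold.n_elem != B)
    stop("dimension mismatch");
  arma::vec n1(F), n2(F), df(F), invn(F);
  arma::mat pat_inc = include.each_row() % patient.t();  // F x n
  for (arma::uword f = 0; f < F; ++f) {
    double nf = arma::accu(include.row(f));
    n1[f] = arma::accu(pat_inc.row(f));
    n2[f] = nf - n1[f];
    if (n1[f] < 2 || n2[f] < 2) stop("a fold has fewer than 2 per group");
    df[f] = nf - 2.0;
    invn[f] = 1.0 / n1[f] + 1.0 / n2[f];
  }
  NumericMatrix tobs2(F, E);
  IntegerMatrix count(F, E);

  for (arma::uword lo = 0; lo < E; lo += block) {
    arma::uword hi = std::min(E, lo + arma::uword(block)) - 1;
    const arma::uword blk = hi - lo + 1;
    arma::mat Xb = X.cols(lo, hi);
    arma::mat X2b = arma::square(Xb);
    arma::mat tot = include * Xb;     // F x blk per-fold totals
    arma::mat totsq = include * X2b;
    arma::mat s1o = pat_inc * Xb;     // observed patient sums per fold
    arma::mat q1o = pat_inc * X2b;
    arma::mat S1 = P * Xb;            // B x blk permuted patient sums
    // |group-mean difference| threshold per fold and edge
    arma::mat thr(F, blk);
    for (arma::uword c = 0; c < blk; ++c) {
      for (arma::uword f = 0; f < F; ++f) {
        double tiny = 1e-14 * (totsq(f, c) + 1e-300);
        tobs2(f, lo + c) = t2_stat(s1o(f, c), q1o(f, c), tot(f, c),
                                   totsq(f, c), n1[f], n2[f], df[f], invn[f],
                                   tiny);
        double d = s1o(f, c) / n1[f] - (tot(f, c) - s1o(f, c)) / n2[f];
        thr(f, c) = std::abs(d);
      }
    }
    for (arma::uword c = 0; c < blk; ++c) {
      for (arma::uword b = 0; b < B; ++b) {
        arma::uword f = arma::uword(fold[b] - 1);
        double d = S1(b, c) * invn[f] - tot(f, c) / n2[f];
        if (std::abs(d) >= thr(f, c)) ++count(f, lo + c);
      }
    }
  }
  return List::create(_["tobs2"] = tobs2, _["count"] = count);
}
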