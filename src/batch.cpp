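// Batched Monte-Carlo kernels for the rejection-sampling baseline.
// Validity-rate estimation needs millions of small symmetric eigenvalue
// problems; the construction itself is trivial (uniform strictly-lower
// draws, symmetrize, unit diagonal) so the whole attempt loop lives here.
// Uniform variates come from R's RNG stream, so results are reproducible
// from set.seed() and bit-identical to the equivalent R-level loop, which
// draws the strictly lower triangle in column-major order.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline void fill_rs_matrix(arma::mat &C, int n, bool rounding) {
  for (int j = 0; j < n; ++j) {
    C(j, j) = 1.0;
    for (int i = j + 1; i < n; ++i) {
      double u = R::unif_rand();
      if (rounding) u = std::round(u * 1e8) / 1e8;
      double c = -1.0 + 2.0 * u;
      C(i, j) = c;
      C(j, i) = c;
    }
  }
}

//' Minimum eigenvalues of repeated rejection-sampling attempts
//'
//' Draws \code{reps} symmetric unit-diagonal matrices with strictly-lower
//' entries uniform on \[-1, 1\] (optionally rounded to 8 decimals) and
//' returns each attempt's minimum eigenvalue.
//'
//' @param n matrix dimension.
//' @param reps number of attempts.
//' @param rounding apply the 8-decimal rounding dialect.
//' @return numeric vector of length \code{reps}.
//' @keywords internal
// [[Rcpp::export]]
NumericVector cpp_rs_mineig(int n, int reps, bool rounding) {
  if (n < 2 || reps < 1) stop("need n >= 2 and reps >= 1");
  NumericVector out(reps);
  arma::mat C(n, n, arma::fill::zeros);
  arma::vec ev;
  for (int r = 0; r < reps; ++r) {
    fill_rs_matrix(C, n, rounding);
    arma::eig_sym(ev, C);
    out[r] = ev(0);
  }
  return out;
}

//' Collect valid rejection-sampling matrices
//'
//' Repeats the rejection-sampling construction until \code{count} matrices
//' with non-negative minimum eigenvalue have been accepted.
//'
//' @param n matrix dimension.
//' @param count number of valid matrices to collect.
//' @param rounding apply the 8-decimal rounding dialect.
//' @param max_total_attempts abort after this many attempts (0 = no cap).
//' @return list with \code{matrices} (count x n*n, rows are column-major
//'   vectorized matrices), \code{attempts} per accepted matrix, and
//'   \code{total_attempts}.
//' @keywords internal
// [[Rcpp::export]]
List cpp_rs_collect(int n, int count, bool rounding,
                    double max_total_attempts = 0) {
  if (n < 2 || count < 1) stop("need n >= 2 and count >= 1");
  NumericMatrix mats(count, n * n);
  IntegerVector attempts(count);
  arma::mat C(n, n, arma::fill::zeros);
  arma::vec ev;
  double total = 0;
  int got = 0, since = 0;
  while (got < count) {
    if (max_total_attempts > 0 && total >= max_total_attempts) {
      stop("rejection sampling attempt budget exhausted after %g attempts", total);
    }
    ++total;
    ++since;
    fill_rs_matrix(C, n, rounding);
    arma::eig_sym(ev, C);
    if (ev(0) >= 0.0) {
      for (int j = 0; j < n; ++j)
        for (int i = 0; i < n; ++i) mats(got, j * n + i) = C(i, j);
      attempts[got] = since;
      since = 0;
      ++got;
    }
  }
  return List::create(_["matrices"] = mats, _["attempts"] = attempts,
                      _["total_attempts"] = total);
}
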