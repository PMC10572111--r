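// NIPALS PLS1 kernel and cross-validation loop.
// PLS1 needs no iteration per factor: each latent direction is extracted
// in closed form, so the fit is deterministic.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Core NIPALS on (already validated) data. Fills W, P (p x A), q (A),
// and per-truncation regression vectors B (p x A); returns the number of
// factors actually extracted (X may deflate to zero first).
static int nipals_core(mat X, vec y, int max_factors,
                       mat &W, mat &P, vec &q, mat &B,
                       rowvec &x_mean, double &y_mean) {
  const int p = X.n_cols;
  x_mean = mean(X, 0);
  y_mean = mean(y);
  X.each_row() -= x_mean;
  y -= y_mean;

  W.zeros(p, max_factors);
  P.zeros(p, max_factors);
  q.zeros(max_factors);
  int a_done = 0;
  for (int a = 0; a < max_factors; ++a) {
    vec w = X.t() * y;
    double nw = norm(w);
    if (nw < 1e-12) break;
    w /= nw;
    vec t = X * w;
    double tt = dot(t, t);
    if (tt < 1e-24) break;
    vec pl = X.t() * t / tt;
    double qa = dot(y, t) / tt;
    X -= t * pl.t();
    y -= qa * t;
    W.col(a) = w;
    P.col(a) = pl;
    q(a) = qa;
    ++a_done;
  }
  if (a_done == 0) return 0;

  // B_a = W_a (P_a' W_a)^{-1} q_a via the incremental R = W (P'W)^{-1}
  B.zeros(p, a_done);
  mat R(p, a_done, fill::zeros);
  for (int a = 0; a < a_done; ++a) {
    vec r = W.col(a);
    if (a > 0) {
      r -= R.cols(0, a - 1) * (P.cols(0, a - 1).t() * W.col(a));
    }
    R.col(a) = r;
    B.col(a) = (a == 0) ? vec(r * q(0)) : vec(B.col(a - 1) + r * q(a));
  }
  return a_done;
}

// [[Rcpp::export]]
Rcpp::List nipals_pls1(const arma::mat &X, const arma::vec &y,
                       int max_factors) {
  mat W, P, B;
  vec q;
  rowvec x_mean;
  double y_mean;
  int a_done = nipals_core(X, y, max_factors, W, P, q, B, x_mean, y_mean);
  if (a_done == 0) {
    Rcpp::stop("No PLS factor could be extracted (X'y is zero).");
  }
  return Rcpp::List::create(
      Rcpp::Named("weights") = W.cols(0, a_done - 1),
      Rcpp::Named("loadings") = P.cols(0, a_done - 1),
      Rcpp::Named("q") = q.subvec(0, a_done - 1),
      Rcpp::Named("coefficients") = B,
      Rcpp::Named("x_mean") = x_mean.t(),
      Rcpp::Named("y_mean") = y_mean,
      Rcpp::Named("n_factors") = a_done);
}

// Held-out predictions for every factor truncation 1..max_factors.
// folds: 1-based fold label per sample. Truncations beyond a fold's
// extractable factor count reuse its largest feasible one.
// [[Rcpp::export]]
arma::mat pls_cv_preds(const arma::mat &X, const arma::vec &y,
                       int max_factors, const arma::ivec &folds) {
  const int n = X.n_rows;
  mat preds(n, max_factors, fill::value(datum::nan));
  ivec labels = unique(folds);
  for (uword f = 0; f < labels.n_elem; ++f) {
    uvec hold = find(folds == labels(f));
    uvec train = find(folds != labels(f));
    int cap = std::min((int)train.n_elem - 1,
                       std::min((int)X.n_cols, max_factors));
    if (cap < 1) Rcpp::stop("A fold leaves too few training samples.");
    mat W, P, B;
    vec q;
    rowvec x_mean;
    double y_mean;
    int a_done = nipals_core(X.rows(train), y(train), cap, W, P, q, B,
                             x_mean, y_mean);
    if (a_done == 0) Rcpp::stop("No PLS factor could be extracted in a fold.");
    mat Xh = X.rows(hold);
    Xh.each_row() -= x_mean;
    mat ph = Xh * B; // n_hold x a_done
    for (int a = 0; a < max_factors; ++a) {
      int a_use = std::min(a, a_done - 1);
      preds(hold, uvec{(uword)a}) = y_mean + ph.col(a_use);
    }
  }
  return preds;
}
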