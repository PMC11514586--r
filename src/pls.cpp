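// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Column preprocessing. scaling: 0 = none (centre only), 1 = autoscale
// (unit variance, sd with n-1 denominator), 2 = pareto (sqrt sd).
// Constant columns get scale 1 so they centre to zero and drop out.
static void preprocess(const arma::mat &X, const arma::vec &y, int scaling,
                       arma::mat &Xs, arma::vec &ys, arma::rowvec &mx,
                       arma::rowvec &sx, double &my) {
  mx = arma::mean(X, 0);
  sx.set_size(X.n_cols);
  sx.ones();
  if (scaling > 0) {
    arma::rowvec sd = arma::stddev(X, 0, 0);  // n-1 denominator
    for (arma::uword j = 0; j < X.n_cols; ++j) {
      double s = (scaling == 1) ? sd[j] : std::sqrt(sd[j]);
      sx[j] = (s > 1e-12) ? s : 1.0;
    }
  }
  Xs = X.each_row() - mx;
  Xs.each_row() /= sx;
  my = arma::mean(y);
  ys = y - my;
}

// NIPALS PLS1 on preprocessed data. Returns number of components actually
// extracted (can fall short of A when the residual degenerates).
static int nipals(const arma::mat &Xs, const arma::vec &ys, int A,
                  arma::mat &W, arma::mat &P, arma::vec &q, arma::mat &T) {
  const arma::uword n = Xs.n_rows, p = Xs.n_cols;
  W.set_size(p, A); P.set_size(p, A); q.set_size(A); T.set_size(n, A);
  arma::mat E = Xs;
  arma::vec f = ys;
  int a = 0;
  for (; a < A; ++a) {
    arma::vec w = E.t() * f;
    double nw = arma::norm(w);
    if (nw < 1e-12) break;
    w /= nw;
    arma::vec t = E * w;
    double tt = arma::dot(t, t);
    if (tt < 1e-12) break;
    arma::vec pl = E.t() * t / tt;
    double qa = arma::dot(f, t) / tt;
    W.col(a) = w; P.col(a) = pl; q[a] = qa; T.col(a) = t;
    E -= t * pl.t();
    f -= qa * t;
  }
  if (a < A) { W = W.head_cols(a); P = P.head_cols(a); q = q.head(a); T = T.head_cols(a); }
  return a;
}

static arma::vec pls_coef_scaled(const arma::mat &W, const arma::mat &P,
                                 const arma::vec &q) {
  if (W.n_cols == 0) return arma::zeros<arma::vec>(W.n_rows);
  arma::mat PtW = P.t() * W;
  return W * arma::solve(PtW, q);
}

// [[Rcpp::export]]
List cpp_pls_fit(const arma::mat &X, const arma::vec &y, int A, int scaling) {
  arma::mat Xs; arma::vec ys; arma::rowvec mx, sx; double my;
  preprocess(X, y, scaling, Xs, ys, mx, sx, my);
  arma::mat W, P, T; arma::vec q;
  int used = nipals(Xs, ys, A, W, P, q, T);
  arma::vec bs = pls_coef_scaled(W, P, q);
  arma::vec braw = bs / sx.t();
  double b0 = my - arma::dot(braw, mx.t());
  arma::vec fitted = X * braw + b0;
  return List::create(
      _["weights"] = W, _["loadings"] = P, _["y_loadings"] = q,
      _["scores"] = T, _["ncomp_used"] = used,
      _["coef_scaled"] = bs, _["coefficients"] = braw, _["intercept"] = b0,
      _["x_means"] = arma::rowvec(mx), _["x_scales"] = arma::rowvec(sx),
      _["y_mean"] = my, _["fitted"] = fitted);
}

// Naive leave-one-out: refit from scratch on every fold (no deflation
// shortcuts), predict the held-out row with the fold model.
// [[Rcpp::export]]
NumericVector cpp_loo_predictions(const arma::mat &X, const arma::vec &y,
                                  int A, int scaling) {
  const arma::uword n = X.n_rows;
  NumericVector pred(n);
  for (arma::uword i = 0; i < n; ++i) {
    arma::uvec keep(n - 1);
    arma::uword k = 0;
    for (arma::uword j = 0; j < n; ++j) if (j != i) keep[k++] = j;
    arma::mat Xi = X.rows(keep);
    arma::vec yi = y.elem(keep);
    arma::mat Xs; arma::vec ys; arma::rowvec mx, sx; double my;
    preprocess(Xi, yi, scaling, Xs, ys, mx, sx, my);
    arma::mat W, P, T; arma::vec q;
    nipals(Xs, ys, A, W, P, q, T);
    arma::vec bs = pls_coef_scaled(W, P, q);
    arma::vec braw = bs / sx.t();
    double b0 = my - arma::dot(braw, mx.t());
    pred[i] = arma::dot(X.row(i), braw) + b0;
  }
  return pred;
}
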