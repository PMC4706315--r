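// Penalized IRLS for ridge (L2) logistic regression.
//
// Objective (what every routine here minimizes):
//   f(b0, beta) = (1/n) * sum_i log(1 + exp(-(2 y_i - 1) * eta_i))
//                 + (lambda / 2) * ||beta||^2,    eta = b0 + Z beta
// with y in {0,1}, Z the column-standardized design, and the intercept
// unpenalized. Coefficients are returned on the standardized scale together
// with the centering/scaling constants, so predictions on raw features are
// exact.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static void standardize(const mat& X, mat& Z, rowvec& ctr, rowvec& scl) {
  ctr = mean(X, 0);
  scl = stddev(X, 0, 0);          // sample sd (n-1 denominator)
  scl.elem(find(scl <= 0)).fill(1.0);
  Z = X.each_row() - ctr;
  Z.each_row() /= scl;
}

static double neg_loglik_mean(const vec& eta, const vec& y) {
  // numerically stable mean binomial deviance/2: log(1+e^eta) - y*eta
  vec a = eta;
  vec out(eta.n_elem);
  for (uword i = 0; i < eta.n_elem; ++i) {
    double e = eta[i];
    double lse = e > 0 ? e + std::log1p(std::exp(-e)) : std::log1p(std::exp(e));
    out[i] = lse - y[i] * e;
  }
  return mean(out);
}

// Newton iterations with step halving on the penalized objective.
static void irls_fit(const mat& Z, const vec& y, double lambda,
                     double& b0, vec& beta, double tol, int maxit) {
  const uword n = Z.n_rows, p = Z.n_cols;
  double obj = neg_loglik_mean(b0 + Z * beta, y) + 0.5 * lambda * dot(beta, beta);
  for (int it = 0; it < maxit; ++it) {
    vec eta = b0 + Z * beta;
    vec mu = 1.0 / (1.0 + exp(-eta));
    vec w = mu % (1.0 - mu);
    w.elem(find(w < 1e-10)).fill(1e-10);
    vec r = mu - y;

    // gradient and Hessian of the mean-scale objective, intercept first
    vec g(p + 1);
    g[0] = mean(r);
    g.subvec(1, p) = Z.t() * r / (double)n + lambda * beta;
    mat H(p + 1, p + 1);
    H(0, 0) = mean(w);
    rowvec zw = (w.t() * Z) / (double)n;
    H.submat(0, 1, 0, p) = zw;
    H.submat(1, 0, p, 0) = zw.t();
    H.submat(1, 1, p, p) = Z.t() * (Z.each_col() % w) / (double)n
                           + lambda * eye(p, p);

    vec step = solve(H, g, solve_opts::likely_sympd);
    double t = 1.0;
    double new_obj = obj;
    double nb0 = b0; vec nbeta = beta;
    for (int h = 0; h < 30; ++h) {
      nb0 = b0 - t * step[0];
      nbeta = beta - t * step.subvec(1, p);
      new_obj = neg_loglik_mean(nb0 + Z * nbeta, y)
                + 0.5 * lambda * dot(nbeta, nbeta);
      if (new_obj <= obj + 1e-14) break;
      t *= 0.5;
    }
    double delta = std::abs(obj - new_obj);
    b0 = nb0; beta = nbeta; obj = new_obj;
    if (delta < tol * (std::abs(obj) + tol)) break;
  }
}

// [[Rcpp::export(name = ".ridge_irls_cpp")]]
Rcpp::List ridge_irls_cpp(const arma::mat& X, const arma::vec& y,
                          double lambda, double tol = 1e-12, int maxit = 200) {
  mat Z; rowvec ctr, scl;
  standardize(X, Z, ctr, scl);
  double b0 = 0.0; vec beta(X.n_cols, fill::zeros);
  irls_fit(Z, y, lambda, b0, beta, tol, maxit);
  double dev = neg_loglik_mean(b0 + Z * beta, y);
  return Rcpp::List::create(
    Rcpp::Named("intercept") = b0,
    Rcpp::Named("beta") = beta,
    Rcpp::Named("center") = ctr,
    Rcpp::Named("scale") = scl,
    Rcpp::Named("mean_nll") = dev);
}

// Cross-validated mean deviance over a lambda grid: for each fold, fit on the
// complement (standardized within that training set) along the grid with warm
// starts, accumulate held-out mean negative log-likelihood.
// foldid is 1-based.
// [[Rcpp::export(name = ".ridge_cv_deviance_cpp")]]
arma::vec ridge_cv_deviance_cpp(const arma::mat& X, const arma::vec& y,
                                const arma::ivec& foldid,
                                const arma::vec& lambdas,
                                double tol = 1e-10, int maxit = 100) {
  const int k = foldid.max();
  const uword m = lambdas.n_elem;
  vec dev(m, fill::zeros);
  vec nheld(m, fill::zeros);
  for (int f = 1; f <= k; ++f) {
    uvec test = find(foldid == f);
    uvec train = find(foldid != f);
    mat Xtr = X.rows(train), Xte = X.rows(test);
    vec ytr = y.elem(train), yte = y.elem(test);
    mat Z; rowvec ctr, scl;
    standardize(Xtr, Z, ctr, scl);
    mat Zte = Xte.each_row() - ctr;
    Zte.each_row() /= scl;
    double b0 = 0.0; vec beta(X.n_cols, fill::zeros);
    for (uword j = 0; j < m; ++j) {       // warm starts down the grid
      irls_fit(Z, ytr, lambdas[j], b0, beta, tol, maxit);
      vec eta = b0 + Zte * beta;
      dev[j] += neg_loglik_mean(eta, yte) * (double)test.n_elem;
      nheld[j] += (double)test.n_elem;
    }
  }
  return dev / nheld;
}
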