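// Fast profiled-REML estimation of the random-intercept linear mixed model
//   y = X beta + Z b + e,  b ~ N(0, sigma_b^2 I),  e ~ N(0, sigma^2 I)
// with Z a participant indicator matrix, fitted independently for every
// column of Y (one column per time sample). All columns share X and the
// grouping, so the per-group aggregates of X are computed once; each sample
// then costs a 1-D golden-section search over the variance ratio
// lambda = sigma_b^2 / sigma^2, with every criterion evaluation O(G + p^3)
// via the blockwise Sherman-Morrison identity
//   V^{-1} = I - sum_g  lambda/(1 + lambda n_g) * 1_g 1_g^T.
// This matches what a general mixed-model fitter returns for this model
// (same REML criterion), at a tiny fraction of the cost, which is what the
// per-sample localization and permutation engines need.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

struct RIWork {
  // aggregates for one response vector (possibly a subset of rows)
  mat XtX;      // p x p
  mat Sg;       // G x p, per-group column sums of X
  vec ng;       // G, per-group row counts
  vec ty;       // G, per-group sums of y
  vec Xty;      // p
  double yty;
  double n;
};

// profiled REML deviance (up to a constant) at variance ratio lam,
// and on request the GLS solution at lam
static double reml_crit(const RIWork& w, double lam, int p,
                        vec* beta_out, mat* cov_out, double* sig2_out) {
  vec wg = lam / (1.0 + lam * w.ng);          // G
  mat A = w.XtX - w.Sg.t() * (w.Sg.each_col() % wg);
  vec b = w.Xty - w.Sg.t() * (w.ty % wg);
  double q = w.yty - dot(wg, square(w.ty));
  mat Ainv;
  if (!inv_sympd(Ainv, A)) {
    if (!pinv(Ainv, A)) return datum::inf;
  }
  vec beta = Ainv * b;
  double r2 = q - dot(b, beta);
  if (r2 <= 0) r2 = 1e-300;
  double nmp = w.n - p;
  double logdetV = accu(log1p(lam * w.ng));
  double sldA, signA;
  log_det(sldA, signA, A);
  double crit = logdetV + sldA + nmp * std::log(r2);
  if (beta_out) {
    *beta_out = beta;
    *sig2_out = r2 / nmp;
    *cov_out = (*sig2_out) * Ainv;
  }
  return crit;
}

// [[Rcpp::export]]
Rcpp::List ri_lmm_fit(const arma::mat& Y, const arma::mat& X,
                      const arma::ivec& g, int G) {
  const int n = Y.n_rows, S = Y.n_cols, p = X.n_cols;
  if ((int)X.n_rows != n || (int)g.n_elem != n)
    Rcpp::stop("dimension mismatch between Y, X and grouping");

  // full-data aggregates, reused for every sample without missing values
  RIWork full;
  full.XtX = X.t() * X;
  full.Sg.zeros(G, p);
  full.ng.zeros(G);
  for (int i = 0; i < n; ++i) {
    int gi = g[i];
    if (gi < 0 || gi >= G) Rcpp::stop("group index out of range");
    full.Sg.row(gi) += X.row(i);
    full.ng[gi] += 1.0;
  }

  mat beta(p, S, fill::value(datum::nan));
  mat se(p, S, fill::value(datum::nan));
  vec sigma2(S, fill::value(datum::nan));
  vec lambda(S, fill::value(datum::nan));
  ivec n_used(S, fill::zeros);

  const double lo = -13.0, hi = 13.0;          // bounds on log(lambda)
  const double gr = (std::sqrt(5.0) - 1.0) / 2.0;

  for (int s = 0; s < S; ++s) {
    const vec y = Y.col(s);
    uvec ok = find_finite(y);
    RIWork w;
    vec ysub;
    if ((int)ok.n_elem == n) {
      w = full;
      w.ty.zeros(G);
      for (int i = 0; i < n; ++i) w.ty[g[i]] += y[i];
      w.Xty = X.t() * y;
      w.yty = dot(y, y);
      w.n = n;
    } else {
      if ((int)ok.n_elem <= p + 1) continue;   // too few rows to fit
      ysub = y(ok);
      mat Xs = X.rows(ok);
      w.XtX = Xs.t() * Xs;
      w.Sg.zeros(G, p);
      w.ng.zeros(G);
      w.ty.zeros(G);
      for (uword k = 0; k < ok.n_elem; ++k) {
        int gi = g[ok[k]];
        w.Sg.row(gi) += Xs.row(k);
        w.ng[gi] += 1.0;
        w.ty[gi] += ysub[k];
      }
      w.Xty = Xs.t() * ysub;
      w.yty = dot(ysub, ysub);
      w.n = ok.n_elem;
    }

    // golden-section search on u = log(lambda); REML profile is smooth and
    // in practice unimodal; endpoints approximate OLS (u -> -inf) and the
    // group-saturated fit (u -> +inf)
    double a = lo, bnd = hi;
    double c = bnd - gr * (bnd - a), d = a + gr * (bnd - a);
    double fc = reml_crit(w, std::exp(c), p, nullptr, nullptr, nullptr);
    double fd = reml_crit(w, std::exp(d), p, nullptr, nullptr, nullptr);
    for (int it = 0; it < 80 && (bnd - a) > 1e-9; ++it) {
      if (fc < fd) {
        bnd = d; d = c; fd = fc;
        c = bnd - gr * (bnd - a);
        fc = reml_crit(w, std::exp(c), p, nullptr, nullptr, nullptr);
      } else {
        a = c; c = d; fc = fd;
        d = a + gr * (bnd - a);
        fd = reml_crit(w, std::exp(d), p, nullptr, nullptr, nullptr);
      }
    }
    double u = 0.5 * (a + bnd);
    double lam = std::exp(u);
    // boundary check: lambda ~ 0 (no group variance) may beat the interior
    double f_in = reml_crit(w, lam, p, nullptr, nullptr, nullptr);
    double f_0 = reml_crit(w, 0.0, p, nullptr, nullptr, nullptr);
    if (f_0 < f_in) lam = 0.0;

    vec bhat;
    mat covb;
    double sig2;
    double crit = reml_crit(w, lam, p, &bhat, &covb, &sig2);
    if (!std::isfinite(crit)) continue;
    beta.col(s) = bhat;
    se.col(s) = sqrt(covb.diag());
    sigma2[s] = sig2;
    lambda[s] = lam;
    n_used[s] = (int)w.n;
  }

  return Rcpp::List::create(
    Rcpp::Named("beta") = beta,
    Rcpp::Named("se") = se,
    Rcpp::Named("sigma2") = sigma2,
    Rcpp::Named("lambda") = lambda,
    Rcpp::Named("n_used") = n_used);
}
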