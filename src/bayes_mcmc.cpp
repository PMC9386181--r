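// Gibbs sampler for mixture-prior whole-genome regression (Bayes B / Bayes C).
//
// Model: y = X b + sum_j a_j beta_j delta_j + e
//   delta_j ~ Bernoulli(1 - pi), beta_j | delta_j = 1 ~ N(0, sigma2_j),
//   sigma2_j per-locus scaled-inv-chisq(nu_beta, s2_beta) for Bayes B,
//   a single shared sigma2_beta for Bayes C; e ~ N(0, sigma2_e I).
// delta_j is updated from its marginal odds with beta_j integrated out
// (collapsed update), then beta_j is drawn when delta_j = 1.
//
// Uses R's RNG throughout so set.seed() in R gives full determinism.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double rinvchisq(double nu, double s2) {
  // scaled inverse chi-square: nu * s2 / chisq(nu)
  return nu * s2 / R::rchisq(nu);
}

// [[Rcpp::export(name = ".bayes_mcmc_cpp")]]
List bayes_mcmc_cpp(const arma::mat& A,        // n x p centred SNP covariates
                    const arma::mat& X,        // n x q fixed-effect design (q >= 0)
                    const arma::vec& y,
                    double pi0,
                    int n_iter, int burn_in,
                    double nu_beta, double s2_beta,
                    double nu_e, double s2_e,
                    bool bayesB,
                    double fix_sigma2_e,       // <= 0 means "sample it"
                    double fix_sigma2_beta,    // <= 0 means "sample it"
                    const arma::uvec& window,  // 0-based window index per SNP
                    int n_windows,
                    bool save_beta) {
  const int n = A.n_rows, p = A.n_cols, q = X.n_cols;
  if ((int) y.n_elem != n) stop("length(y) != nrow(A)");
  if ((int) window.n_elem != p) stop("window assignment length != n_snps");

  arma::vec cj(p);
  for (int j = 0; j < p; ++j) cj(j) = arma::dot(A.col(j), A.col(j));

  arma::mat XtX, Rchol;
  if (q > 0) {
    XtX = X.t() * X;
    if (!arma::chol(Rchol, XtX)) stop("fixed-effect design is rank deficient");
  }

  arma::vec beta(p, arma::fill::zeros);
  arma::ivec delta(p, arma::fill::zeros);
  arma::vec sigma2_j(p);
  double sigma2_beta = (fix_sigma2_beta > 0) ? fix_sigma2_beta : s2_beta;
  sigma2_j.fill(sigma2_beta);
  double sigma2_e = (fix_sigma2_e > 0) ? fix_sigma2_e : s2_e;
  if (sigma2_e <= 0) sigma2_e = arma::var(y) / 2.0;
  arma::vec b(q, arma::fill::zeros);
  arma::vec r = y;  // residual y - Xb - A (beta . delta); starts at y since all 0

  const int n_keep = n_iter - burn_in;
  arma::vec beta_sum(p, arma::fill::zeros), delta_sum(p, arma::fill::zeros);
  arma::vec b_sum(std::max(q, 1), arma::fill::zeros);
  arma::vec s2g_samples(n_keep), s2e_samples(n_keep);
  arma::mat wvar_samples(n_keep, n_windows, arma::fill::zeros);
  arma::mat beta_samples;
  if (save_beta) beta_samples.set_size(n_keep, p);
  arma::mat Gw(n, n_windows);
  const double log_prior_odds = std::log((1.0 - pi0) / pi0);

  RNGScope scope;

  for (int it = 0; it < n_iter; ++it) {
    // --- fixed effects: joint draw b | rest ~ N((X'X)^-1 X'w, sigma2_e (X'X)^-1)
    if (q > 0) {
      arma::vec w = r + X * b;
      arma::vec bhat = arma::solve(XtX, X.t() * w, arma::solve_opts::likely_sympd);
      arma::vec z(q);
      for (int k = 0; k < q; ++k) z(k) = R::norm_rand();
      b = bhat + std::sqrt(sigma2_e) * arma::solve(arma::trimatu(Rchol), z);
      r = w - X * b;
    }

    // --- SNP effects, locus by locus
    for (int j = 0; j < p; ++j) {
      if (cj(j) <= 0) { delta(j) = 0; beta(j) = 0; continue; }
      double s2j;
      if (bayesB) {
        if (fix_sigma2_beta > 0) s2j = fix_sigma2_beta;
        else if (delta(j) == 1)
          s2j = rinvchisq(nu_beta + 1.0,
                          (nu_beta * s2_beta + beta(j) * beta(j)) / (nu_beta + 1.0));
        else s2j = rinvchisq(nu_beta, s2_beta);
        sigma2_j(j) = s2j;
      } else {
        s2j = sigma2_beta;
      }

      const double beta_old = beta(j);
      double rhs = arma::dot(A.col(j), r) + cj(j) * beta_old;
      if (!std::isfinite(rhs))
        stop("non-finite likelihood term at iteration %d, locus %d", it + 1, j + 1);
      const double v1 = cj(j) * s2j + sigma2_e;
      const double log_bf = 0.5 * (std::log(sigma2_e / v1)
                                   + rhs * rhs * s2j / (sigma2_e * v1));
      const double log_odds = log_prior_odds + log_bf;
      const double p1 = 1.0 / (1.0 + std::exp(-log_odds));
      const bool incl = (R::unif_rand() < p1);

      if (incl) {
        const double denom = cj(j) + sigma2_e / s2j;
        const double mean = rhs / denom;
        const double sd = std::sqrt(sigma2_e / denom);
        const double beta_new = mean + sd * R::norm_rand();
        if (beta_old != beta_new) r += A.col(j) * (beta_old - beta_new);
        beta(j) = beta_new;
        delta(j) = 1;
      } else {
        if (beta_old != 0.0) r += A.col(j) * beta_old;
        beta(j) = 0.0;
        delta(j) = 0;
      }
    }

    // --- variance components
    if (!bayesB && fix_sigma2_beta <= 0) {
      int m = 0; double ss = 0.0;
      for (int j = 0; j < p; ++j) if (delta(j)) { ++m; ss += beta(j) * beta(j); }
      sigma2_beta = rinvchisq(nu_beta + m, (nu_beta * s2_beta + ss) / (nu_beta + m));
    }
    if (fix_sigma2_e <= 0)
      sigma2_e = rinvchisq(nu_e + n, (nu_e * s2_e + arma::dot(r, r)) / (nu_e + n));

    // --- accumulate posterior summaries
    if (it >= burn_in) {
      const int t = it - burn_in;
      beta_sum += beta;
      for (int j = 0; j < p; ++j) delta_sum(j) += delta(j);
      if (q > 0) b_sum += b;
      Gw.zeros();
      for (int j = 0; j < p; ++j)
        if (delta(j)) Gw.col(window(j)) += A.col(j) * beta(j);
      arma::vec g = arma::sum(Gw, 1);
      s2g_samples(t) = arma::var(g);
      s2e_samples(t) = sigma2_e;
      for (int w = 0; w < n_windows; ++w)
        wvar_samples(t, w) = arma::var(Gw.col(w));
      if (save_beta) beta_samples.row(t) = beta.t();
    }
    if (it % 1000 == 0) Rcpp::checkUserInterrupt();
  }

  List out = List::create(
    _["beta_mean"] = beta_sum / n_keep,
    _["inclusion_prob"] = delta_sum / n_keep,
    _["b_mean"] = (q > 0) ? NumericVector(wrap(b_sum / n_keep)) : NumericVector(0),
    _["sigma2_g_samples"] = s2g_samples,
    _["sigma2_e_samples"] = s2e_samples,
    _["window_var_samples"] = wvar_samples);
  if (save_beta) out["beta_samples"] = beta_samples;
  return out;
}
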