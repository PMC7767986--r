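// Four-component normal-mixture SNP-effect model: EM warm start and
// single-site Gibbs sampler. Residual variances are per-record
// sigma2_e / w_i (DRP weights as inverse residual-variance multipliers).
// Randomness comes from R's RNG (seed set in R), so chains are
// reproducible from R-level seeds.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Gibbs draw / EM responsibility for one SNP given its weighted
// cross-products. rhs = W_j' R r_full / sigma2e, C = d_j / sigma2e.
static inline void component_logliks(double rhs, double C,
                                     const arma::vec &log_pi,
                                     const arma::vec &sigma2k,
                                     arma::vec &logl) {
  logl[0] = log_pi[0];
  for (int k = 1; k < 4; ++k) {
    if (sigma2k[k] <= 0.0) { logl[k] = -1e300; continue; }
    double vk = 1.0 / (C + 1.0 / sigma2k[k]);
    logl[k] = log_pi[k] + 0.5 * std::log(vk / sigma2k[k]) +
      0.5 * rhs * rhs * vk;
  }
}

static arma::vec sample_fixed_effects(const arma::mat &X,
                                      const arma::mat &XtRX_chol,
                                      const arma::vec &XtR_target,
                                      double sigma2e, bool draw) {
  // b | . ~ N((X'RX)^-1 X'R t, sigma2e (X'RX)^-1), t = y - Wv
  arma::vec mean_b = arma::solve(arma::trimatu(XtRX_chol),
                    arma::solve(arma::trimatl(XtRX_chol.t()), XtR_target));
  if (!draw) return mean_b;
  arma::vec z(mean_b.n_elem);
  for (arma::uword i = 0; i < z.n_elem; ++i) z[i] = R::norm_rand();
  // chol upper U with X'RX = U'U: b = mean + sqrt(sigma2e) U^-1 z
  arma::vec dev = arma::solve(arma::trimatu(XtRX_chol), z);
  return mean_b + std::sqrt(sigma2e) * dev;
}

// [[Rcpp::export(name = ".bayesr_gibbs_cpp")]]
List bayesr_gibbs_cpp(const arma::vec &y, const arma::mat &W,
                      const arma::mat &X, const arma::vec &w,
                      const arma::vec &pi, const arma::vec &sigma2k,
                      double sigma2e, int iters, int burnin,
                      arma::vec v, bool sample_sigma2e,
                      double df_prior, double scale_prior) {
  const int n = y.n_elem, m = W.n_cols, p = X.n_cols;
  arma::vec log_pi = arma::log(pi + 1e-300);
  arma::vec d(m);                       // d_j = sum_i w_i W_ij^2
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += w[i] * W(i, j) * W(i, j);
    d[j] = s;
  }
  arma::mat XtRX = X.t() * (X.each_col() % w);
  arma::mat XtRX_chol = arma::chol(XtRX);
  arma::mat XtR = (X.each_col() % w).t();
  arma::vec b(p, arma::fill::zeros);
  arma::vec r = y - W * v - X * b;      // current residual
  arma::vec v_sum(m, arma::fill::zeros);
  arma::mat comp_sum(m, 4, arma::fill::zeros);
  arma::vec b_sum(p, arma::fill::zeros);
  double s2e_sum = 0.0;
  arma::vec logl(4), prob(4);
  arma::uvec ord(m);
  int kept = 0;

  for (int it = 0; it < iters; ++it) {
    // (i) fixed effects from their weighted-LS conditional
    arma::vec target = r + X * b;       // y - Wv
    arma::vec b_new = sample_fixed_effects(X, XtRX_chol, XtR * target,
                                           sigma2e, true);
    r += X * (b - b_new);
    b = b_new;
    // (ii) SNP effects in a freshly randomized order
    for (int j = 0; j < m; ++j) ord[j] = j;
    for (int j = m - 1; j > 0; --j) {
      int jj = (int)(unif_rand() * (j + 1));
      if (jj > j) jj = j;
      std::swap(ord[j], ord[jj]);
    }
    bool post_burn = it >= burnin;
    for (int jj = 0; jj < m; ++jj) {
      int j = ord[jj];
      double wr = 0.0;
      for (int i = 0; i < n; ++i) wr += w[i] * W(i, j) * r[i];
      double rhs = (wr + d[j] * v[j]) / sigma2e;
      double C = d[j] / sigma2e;
      component_logliks(rhs, C, log_pi, sigma2k, logl);
      double mx = logl.max();
      prob = arma::exp(logl - mx);
      prob /= arma::accu(prob);
      double u = unif_rand();
      int comp = 0;
      double acc = 0.0;
      for (int k = 0; k < 4; ++k) { acc += prob[k]; if (u <= acc) { comp = k; break; } }
      double v_new = 0.0;
      if (comp > 0) {
        double vk = 1.0 / (C + 1.0 / sigma2k[comp]);
        v_new = rhs * vk + std::sqrt(vk) * R::norm_rand();
      }
      if (v_new != v[j]) {
        double delta = v_new - v[j];
        for (int i = 0; i < n; ++i) r[i] -= W(i, j) * delta;
        v[j] = v_new;
      }
      if (post_burn)  // Rao-Blackwellized component probabilities
        for (int k = 0; k < 4; ++k) comp_sum(j, k) += prob[k];
    }
    // (iii) optional residual-variance update (scaled-inverse-chi-square)
    if (sample_sigma2e) {
      double sse = 0.0;
      for (int i = 0; i < n; ++i) sse += w[i] * r[i] * r[i];
      double df = df_prior + n;
      double chi = R::rchisq(df);
      sigma2e = (sse + df_prior * scale_prior) / chi;
    }
    if (!r.is_finite())
      stop("non-finite residual at Gibbs iteration %d", it + 1);
    if (post_burn) {
      v_sum += v;
      b_sum += b;
      s2e_sum += sigma2e;
      ++kept;
    }
  }
  if (kept == 0) kept = 1;
  return List::create(
    Named("v_hat") = v_sum / kept,
    Named("comp_post") = comp_sum / kept,
    Named("b_hat") = b_sum / kept,
    Named("sigma2_e") = s2e_sum / std::max(kept, 1),
    Named("v_last") = v);
}

// [[Rcpp::export(name = ".bayesr_em_cpp")]]
List bayesr_em_cpp(const arma::vec &y, const arma::mat &W,
                   const arma::mat &X, const arma::vec &w,
                   const arma::vec &pi, const arma::vec &sigma2k,
                   double sigma2e, double tol, int max_iter) {
  const int n = y.n_elem, m = W.n_cols, p = X.n_cols;
  arma::vec log_pi = arma::log(pi + 1e-300);
  arma::vec d(m);
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += w[i] * W(i, j) * W(i, j);
    d[j] = s;
  }
  arma::mat XtRX = X.t() * (X.each_col() % w);
  arma::mat XtRX_chol = arma::chol(XtRX);
  arma::mat XtR = (X.each_col() % w).t();
  arma::vec v(m, arma::fill::zeros), b(p, arma::fill::zeros);
  arma::vec r = y - X * b;
  arma::mat resp(m, 4, arma::fill::zeros);
  resp.col(0).ones();
  arma::vec logl(4), prob(4);
  std::vector<double> norm_hist;
  int it = 0;
  bool converged = false;
  for (it = 0; it < max_iter; ++it) {
    arma::vec target = r + X * b;
    arma::vec b_new = sample_fixed_effects(X, XtRX_chol, XtR * target,
                                           sigma2e, false);
    r += X * (b - b_new);
    b = b_new;
    double max_delta = 0.0;
    for (int j = 0; j < m; ++j) {
      double wr = 0.0;
      for (int i = 0; i < n; ++i) wr += w[i] * W(i, j) * r[i];
      double rhs = (wr + d[j] * v[j]) / sigma2e;
      double C = d[j] / sigma2e;
      component_logliks(rhs, C, log_pi, sigma2k, logl);
      double mx = logl.max();
      prob = arma::exp(logl - mx);
      prob /= arma::accu(prob);
      // posterior-mean effect under the mixture (component 1 contributes 0)
      double v_new = 0.0;
      for (int k = 1; k < 4; ++k) {
        if (sigma2k[k] <= 0.0) continue;
        double vk = 1.0 / (C + 1.0 / sigma2k[k]);
        v_new += prob[k] * rhs * vk;
      }
      double delta = v_new - v[j];
      if (std::abs(delta) > max_delta) max_delta = std::abs(delta);
      if (delta != 0.0) {
        for (int i = 0; i < n; ++i) r[i] -= W(i, j) * delta;
        v[j] = v_new;
      }
      resp.row(j) = prob.t();
    }
    double nrm = arma::norm(v);
    norm_hist.push_back(nrm);
    if (it >= 50 && norm_hist[it - 50] > 0 &&
        nrm > 10.0 * norm_hist[it - 50])
      stop("EM warm start diverging: effect norm grew 10-fold "
           "over 50 iterations");
    if (max_delta < tol) { converged = true; ++it; break; }
  }
  return List::create(Named("v") = v, Named("resp") = resp,
                      Named("b") = b, Named("iterations") = it,
                      Named("converged") = converged);
}
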