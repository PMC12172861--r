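// Gibbs sampler for the hierarchical Bayesian ordered-probit regression:
//   y*_i = x_i' beta + u_subj(i) + u_sb(i) + eps_i,  eps ~ N(0, 1)
//   y_i = k  iff  tau_{k-1} < y*_i <= tau_k          (tau_0 = -Inf, tau_K = Inf)
//   u_subj ~ N(0, sigma_s^2), u_sb ~ N(0, sigma_sb^2) (block nested in subject)
//
// Latent responses are augmented (Albert & Chib 1993). Fixed effects and
// both random-intercept vectors are drawn in ONE Gaussian block from their
// joint conditional, which removes the slow beta-vs-intercept coupling of
// alternating updates (important for between-subject terms like Group).
// Cutpoints use per-component collapsed Metropolis steps on the ordinal
// likelihood with the latent responses integrated out (Cowles 1996); only
// the two adjacent response categories enter each acceptance ratio.
//
// Priors: beta ~ N(0, prior_beta_sd^2), tau ~ N(0, prior_tau_sd^2) (ordered),
// sigma ~ half-Normal(prior_sigma_sd). No intercept; residual SD fixed at 1.
// Uses R's RNG so set.seed() in R makes runs reproducible.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double rtruncnorm(double mu, double sd, double lo, double hi) {
  // inverse-CDF truncated normal draw, guarded in the extreme tails
  double plo = std::isfinite(lo) ? R::pnorm((lo - mu) / sd, 0.0, 1.0, 1, 0) : 0.0;
  double phi = std::isfinite(hi) ? R::pnorm((hi - mu) / sd, 0.0, 1.0, 1, 0) : 1.0;
  if (phi - plo < 1e-14) {
    if (std::isfinite(lo) && mu < lo) return lo + 1e-8 * sd;
    if (std::isfinite(hi) && mu > hi) return hi - 1e-8 * sd;
    return std::isfinite(lo) ? lo + 1e-8 * sd : hi - 1e-8 * sd;
  }
  double u = R::runif(plo, phi);
  double out = mu + sd * R::qnorm(u, 0.0, 1.0, 1, 0);
  if (std::isfinite(lo) && out < lo) out = lo + 1e-10 * sd;
  if (std::isfinite(hi) && out > hi) out = hi - 1e-10 * sd;
  return out;
}

// [[Rcpp::export]]
Rcpp::List ordinal_gibbs_cpp(const arma::ivec& y, const arma::mat& X,
                             const arma::ivec& subj, const arma::ivec& sb,
                             int n_subj, int n_sb, int K,
                             int warmup, int keep,
                             arma::vec beta_init, arma::vec tau,
                             double prior_beta_sd, double prior_tau_sd,
                             double prior_sigma_sd,
                             bool sample_ranef) {
  const int n = y.n_elem, p = X.n_cols, K1 = K - 1;
  if ((int)tau.n_elem != K1) Rcpp::stop("tau has wrong length");

  const int q = sample_ranef ? (p + n_subj + n_sb) : p;

  // stacked design W = [X | Z_subject | Z_subject_block]
  mat W(n, q, fill::zeros);
  W.cols(0, p - 1) = X;
  if (sample_ranef) {
    for (int i = 0; i < n; ++i) {
      W(i, p + subj(i)) = 1.0;
      W(i, p + n_subj + sb(i)) = 1.0;
    }
  }
  const mat WtW = W.t() * W;

  // cell bookkeeping for the recentering sweeps: which subject owns each
  // subject-block cell, and which design columns are constant within cells
  std::vector<std::vector<int>> subj_cells(n_subj);
  mat cell_val(n_sb, p, fill::zeros);
  std::vector<bool> cconst(p, true);
  {
    ivec cell_subj(n_sb); cell_subj.fill(-1);
    ivec seen(n_sb, fill::zeros);
    for (int i = 0; i < n; ++i) {
      int c = sb(i);
      if (cell_subj(c) < 0) {
        cell_subj(c) = subj(i);
        subj_cells[subj(i)].push_back(c);
      }
      if (!seen(c)) { cell_val.row(c) = X.row(i); seen(c) = 1; }
      else {
        for (int j = 0; j < p; ++j) {
          if (std::abs(X(i, j) - cell_val(c, j)) > 1e-12) cconst[j] = false;
        }
      }
    }
  }

  vec theta(q, fill::zeros);
  theta.head(p) = beta_init;
  double sigma_s = 0.5, sigma_sb = 0.5;
  vec ystar(n), eta = W * theta;

  // adaptation state for the cutpoint proposals and sigma random walks
  vec s_tau(K1, fill::value(0.1));
  ivec acc_tau(K1, fill::zeros), try_tau(K1, fill::zeros);
  double ls_s = -1.5, ls_sb = -1.5;
  int acc_sig[2] = {0, 0}, try_sig[2] = {0, 0};

  // row indices per response category (for per-component cutpoint moves)
  std::vector<std::vector<int>> rows_k(K);
  for (int i = 0; i < n; ++i) rows_k[y(i) - 1].push_back(i);

  mat keep_beta(keep, p), keep_tau(keep, K1), keep_sigma(keep, 2);
  mat keep_us(keep, sample_ranef ? n_subj : 1, fill::zeros);
  mat keep_usb(keep, sample_ranef ? n_sb : 1, fill::zeros);
  vec keep_r2(keep);

  Rcpp::RNGScope scope;
  const int total = warmup + keep;
  for (int it = 0; it < total; ++it) {
    // 1. latent responses | theta, tau
    for (int i = 0; i < n; ++i) {
      int k = y(i);
      double lo = (k >= 2) ? tau(k - 2) : -datum::inf;
      double hi = (k <= K1) ? tau(k - 1) : datum::inf;
      ystar(i) = rtruncnorm(eta(i), 1.0, lo, hi);
    }

    // 2. joint block (beta, u_s, u_sb) | y*, sigmas
    mat M = WtW;
    for (int j = 0; j < p; ++j) M(j, j) += 1.0 / (prior_beta_sd * prior_beta_sd);
    if (sample_ranef) {
      for (int j = 0; j < n_subj; ++j)
        M(p + j, p + j) += 1.0 / (sigma_s * sigma_s);
      for (int j = 0; j < n_sb; ++j)
        M(p + n_subj + j, p + n_subj + j) += 1.0 / (sigma_sb * sigma_sb);
    }
    mat R = chol(M);                         // upper triangular
    vec mu = solve(trimatu(R), solve(trimatl(R.t()), W.t() * ystar));
    vec z(q);
    for (int j = 0; j < q; ++j) z(j) = R::norm_rand();
    theta = mu + solve(trimatu(R), z);
    eta = W * theta;

    // 3. random-effect SDs: random-walk MH on log sigma,
    //    half-Normal(prior_sigma_sd) prior + log-scale Jacobian
    if (sample_ranef) {
      for (int which = 0; which < 2; ++which) {
        double& sig = (which == 0) ? sigma_s : sigma_sb;
        double& ls = (which == 0) ? ls_s : ls_sb;
        const int off = (which == 0) ? p : p + n_subj;
        const int len = (which == 0) ? n_subj : n_sb;
        double prop = sig * std::exp(std::exp(ls) * R::norm_rand());
        double lr = 0.0;
        for (int j = 0; j < len; ++j) {
          lr += R::dnorm(theta(off + j), 0.0, prop, 1) -
                R::dnorm(theta(off + j), 0.0, sig, 1);
        }
        lr += R::dnorm(prop, 0.0, prior_sigma_sd, 1) -
              R::dnorm(sig, 0.0, prior_sigma_sd, 1);
        lr += std::log(prop) - std::log(sig);
        ++try_sig[which];
        if (std::log(R::unif_rand()) < lr) { sig = prop; ++acc_sig[which]; }
      }
      if (it < warmup && (it + 1) % 50 == 0) {
        for (int which = 0; which < 2; ++which) {
          double& ls = (which == 0) ? ls_s : ls_sb;
          if (try_sig[which] > 0) {
            double rate = (double)acc_sig[which] / try_sig[which];
            ls += 0.9 * (rate - 0.44);
            ls = std::min(std::max(ls, -7.0), 1.0);
          }
          acc_sig[which] = 0; try_sig[which] = 0;
        }
      }

      // 3b. interweaving (ASIS) scale move: rewrite u = sigma * v with v
      // held fixed, then draw sigma conjugately from the non-centered
      // conditional given y*. The half-Normal prior on sigma is the
      // positive half of a Normal on the unconstrained regression
      // coefficient, so the draw is plain Gaussian and |.| restores the
      // scale. This breaks the sigma-vs-u funnel that the centered MH
      // update alone traverses very slowly.
      for (int which = 0; which < 2; ++which) {
        double& sig = (which == 0) ? sigma_s : sigma_sb;
        const int off = (which == 0) ? p : p + n_subj;
        const int len = (which == 0) ? n_subj : n_sb;
        if (sig < 1e-10) continue;
        double sv2 = 0.0, svr = 0.0;
        for (int i = 0; i < n; ++i) {
          int g = (which == 0) ? subj(i) : sb(i);
          double v = theta(off + g) / sig;
          double r = ystar(i) - (eta(i) - theta(off + g));
          sv2 += v * v;
          svr += v * r;
        }
        double P = sv2 + 1.0 / (prior_sigma_sd * prior_sigma_sd);
        double signew = svr / P + R::norm_rand() / std::sqrt(P);
        double ratio = signew / sig;
        for (int j = 0; j < len; ++j) theta(off + j) *= ratio;
        for (int i = 0; i < n; ++i) {
          int g = (which == 0) ? subj(i) : sb(i);
          eta(i) += (ratio - 1.0) * theta(off + g) / ratio;
        }
        sig = std::fabs(signew);
      }
    }

    // 4. recentering sweeps along likelihood-invariant directions of the
    //    collapsed posterior (y* integrated out; it is redrawn in step 1
    //    before next use). Each direction leaves every tau_k - eta_i fixed,
    //    so the conditional along it is the Gaussian implied by the priors:
    //    (a) global location: all u_subject and all cutpoints shift together;
    //    (b) per design column constant within subject-block cells (Group,
    //        Block, Group x Block): the coefficient trades off against the
    //        cell intercepts;
    //    (c) per subject: the subject intercept trades off against its cells.
    // Without these, between-subject coefficients and cutpoints random-walk
    // along prior-pinned ridges and mix very slowly.
    if (sample_ranef) {
      // (a) global location
      {
        double P = K1 / (prior_tau_sd * prior_tau_sd) +
                   n_subj / (sigma_s * sigma_s);
        double m = -(accu(tau) / (prior_tau_sd * prior_tau_sd) +
                     accu(theta.subvec(p, p + n_subj - 1)) / (sigma_s * sigma_s)) / P;
        double delta = m + R::norm_rand() / std::sqrt(P);
        tau += delta;
        theta.subvec(p, p + n_subj - 1) += delta;
        eta += delta;
      }
      // (b) columns constant within cells: X value per cell precomputed below
      for (int j = 0; j < p; ++j) {
        if (!cconst[j]) continue;
        const vec& cv = cell_val.col(j);
        double P = 1.0 / (prior_beta_sd * prior_beta_sd);
        double m_num = theta(j) / (prior_beta_sd * prior_beta_sd);
        for (int c = 0; c < n_sb; ++c) {
          P += cv(c) * cv(c) / (sigma_sb * sigma_sb);
          m_num -= cv(c) * theta(p + n_subj + c) / (sigma_sb * sigma_sb);
        }
        double delta = m_num / P + R::norm_rand() / std::sqrt(P);
        theta(j) -= delta;
        for (int c = 0; c < n_sb; ++c) theta(p + n_subj + c) += delta * cv(c);
        // eta unchanged: shifts cancel exactly
      }
      // (c) subject vs its cells
      for (int s = 0; s < n_subj; ++s) {
        double P = 1.0 / (sigma_s * sigma_s) +
                    (double)subj_cells[s].size() / (sigma_sb * sigma_sb);
        double m_num = -theta(p + s) / (sigma_s * sigma_s);
        for (int c : subj_cells[s]) {
          m_num += theta(p + n_subj + c) / (sigma_sb * sigma_sb);
        }
        double delta = m_num / P + R::norm_rand() / std::sqrt(P);
        theta(p + s) += delta;
        for (int c : subj_cells[s]) theta(p + n_subj + c) -= delta;
      }
    }

    // 5. cutpoints: per-component collapsed MH. Moving tau_k only changes
    //    the likelihood of observations in categories k and k+1.
    for (int k = 0; k < K1; ++k) {
      double lo = (k > 0) ? tau(k - 1) : -datum::inf;
      double hi = (k < K1 - 1) ? tau(k + 1) : datum::inf;
      double cur = tau(k);
      double prop = rtruncnorm(cur, s_tau(k), lo, hi);
      // proposal normalizers (bounds identical forward/reverse)
      double zf = (std::isfinite(hi) ? R::pnorm((hi - cur) / s_tau(k), 0, 1, 1, 0) : 1.0) -
                  (std::isfinite(lo) ? R::pnorm((lo - cur) / s_tau(k), 0, 1, 1, 0) : 0.0);
      double zr = (std::isfinite(hi) ? R::pnorm((hi - prop) / s_tau(k), 0, 1, 1, 0) : 1.0) -
                  (std::isfinite(lo) ? R::pnorm((lo - prop) / s_tau(k), 0, 1, 1, 0) : 0.0);
      double la = std::log(zf) - std::log(zr) +
                  R::dnorm(prop, 0.0, prior_tau_sd, 1) -
                  R::dnorm(cur, 0.0, prior_tau_sd, 1);
      // category k (upper bound tau_k) and k+1 (lower bound tau_k)
      double lo_k = (k > 0) ? tau(k - 1) : -datum::inf;
      double hi_k1 = (k < K1 - 1) ? tau(k + 1) : datum::inf;
      for (int i : rows_k[k]) {
        double plo = std::isfinite(lo_k) ? R::pnorm(lo_k - eta(i), 0, 1, 1, 0) : 0.0;
        double p_new = R::pnorm(prop - eta(i), 0, 1, 1, 0) - plo;
        double p_old = R::pnorm(cur - eta(i), 0, 1, 1, 0) - plo;
        la += std::log(std::max(p_new, 1e-300)) - std::log(std::max(p_old, 1e-300));
      }
      for (int i : rows_k[k + 1]) {
        double phi = std::isfinite(hi_k1) ? R::pnorm(hi_k1 - eta(i), 0, 1, 1, 0) : 1.0;
        double p_new = phi - R::pnorm(prop - eta(i), 0, 1, 1, 0);
        double p_old = phi - R::pnorm(cur - eta(i), 0, 1, 1, 0);
        la += std::log(std::max(p_new, 1e-300)) - std::log(std::max(p_old, 1e-300));
      }
      ++try_tau(k);
      if (std::log(R::unif_rand()) < la) { tau(k) = prop; ++acc_tau(k); }
    }
    // adapt proposal scales during warmup towards ~44% acceptance
    if (it < warmup && (it + 1) % 50 == 0) {
      for (int k = 0; k < K1; ++k) {
        if (try_tau(k) > 0) {
          double rate = (double)acc_tau(k) / try_tau(k);
          s_tau(k) *= std::exp(0.9 * (rate - 0.44));
          s_tau(k) = std::min(std::max(s_tau(k), 1e-4), 2.0);
        }
        acc_tau(k) = 0; try_tau(k) = 0;
      }
    }

    if (it >= warmup) {
      int d = it - warmup;
      keep_beta.row(d) = theta.head(p).t();
      keep_tau.row(d) = tau.t();
      keep_sigma(d, 0) = sigma_s;
      keep_sigma(d, 1) = sigma_sb;
      if (sample_ranef) {
        keep_us.row(d) = theta.subvec(p, p + n_subj - 1).t();
        keep_usb.row(d) = theta.subvec(p + n_subj, q - 1).t();
      }
      double v = var(eta, 0);
      keep_r2(d) = v / (v + 1.0);
    }
  }

  return Rcpp::List::create(
    Rcpp::Named("beta") = keep_beta,
    Rcpp::Named("tau") = keep_tau,
    Rcpp::Named("sigma") = keep_sigma,
    Rcpp::Named("u_subject") = keep_us,
    Rcpp::Named("u_subject_block") = keep_usb,
    Rcpp::Named("bayes_r2") = keep_r2,
    Rcpp::Named("s_tau") = s_tau);
}
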