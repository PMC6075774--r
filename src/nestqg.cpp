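// Core numerics: tabular relationship matrix and blocked Gibbs samplers for
// pedigree mixed models. All random numbers come from R's RNG so that
// set.seed() in R makes every fit reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Tabular (recursive) method. dam/sire are 1-based positions into the
// topologically ordered id vector; 0 means unknown. Parents precede
// offspring by construction.
// [[Rcpp::export]]
arma::mat tabular_relationship(int n, IntegerVector dam, IntegerVector sire) {
  arma::mat A(n, n, arma::fill::zeros);
  for (int i = 0; i < n; ++i) {
    int d = dam[i] - 1, s = sire[i] - 1;
    for (int j = 0; j < i; ++j) {
      double a = 0.0;
      if (d >= 0) a += 0.5 * A(j, d);
      if (s >= 0) a += 0.5 * A(j, s);
      A(i, j) = A(j, i) = a;
    }
    A(i, i) = 1.0 + ((d >= 0 && s >= 0) ? 0.5 * A(d, s) : 0.0);
  }
  return A;
}

// Variable part of the log conditional probability of a genotype table
// given its allele counts (Levene/Haldane): -sum lgamma(n_g + 1) + H log 2,
// H = number of heterozygotes. Constant terms cancel in comparisons.
static double hwe_table_stat(const std::vector<int>& cnt, int k) {
  double lp = 0.0;
  int H = 0;
  for (int i = 0; i < k; ++i) {
    for (int j = i; j < k; ++j) {
      int c = cnt[i * k + j];
      if (c > 0) {
        lp -= R::lgammafn(c + 1.0);
        if (i != j) H += c;
      }
    }
  }
  return lp + H * M_LN2;
}

// Monte-Carlo exact test for Hardy-Weinberg proportions: permute the 2n
// allele vector, pair consecutive entries, and compare the conditional
// table probability with the observed one. Returns (1 + #{P <= P_obs}) /
// (1 + B).
// [[Rcpp::export]]
double hwe_mc_pvalue(IntegerVector alleles, int n_perm) {
  int m = alleles.size(); // 2n
  int k = 0;
  for (int i = 0; i < m; ++i) k = std::max(k, alleles[i]);
  std::vector<int> a(m);
  for (int i = 0; i < m; ++i) a[i] = alleles[i] - 1;
  std::vector<int> cnt(k * k, 0);
  for (int i = 0; i < m; i += 2) {
    int x = std::min(a[i], a[i + 1]), y = std::max(a[i], a[i + 1]);
    cnt[x * k + y]++;
  }
  double obs = hwe_table_stat(cnt, k);
  int hits = 0;
  for (int b = 0; b < n_perm; ++b) {
    for (int i = m - 1; i > 0; --i) { // Fisher-Yates with R's RNG
      int j = (int)(R::unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(a[i], a[j]);
    }
    std::fill(cnt.begin(), cnt.end(), 0);
    for (int i = 0; i < m; i += 2) {
      int x = std::min(a[i], a[i + 1]), y = std::max(a[i], a[i + 1]);
      cnt[x * k + y]++;
    }
    if (hwe_table_stat(cnt, k) <= obs + 1e-12) hits++;
  }
  return (1.0 + hits) / (1.0 + n_perm);
}

static arma::vec rnorm_vec(int n) {
  arma::vec z(n);
  for (int i = 0; i < n; ++i) z[i] = R::norm_rand();
  return z;
}

// Draw from N(C^{-1} r, C^{-1}) given C (symmetric positive definite).
static arma::vec draw_mvn_canonical(const arma::mat& C, const arma::vec& r) {
  arma::mat U = arma::chol(C); // upper: C = U'U
  arma::vec mu = arma::solve(arma::trimatu(U),
                             arma::solve(arma::trimatl(U.t()), r));
  return mu + arma::solve(arma::trimatu(U), rnorm_vec(C.n_rows));
}

// Inverse-Wishart(df, Psi) via Bartlett decomposition of Wishart(df, Psi^-1).
static arma::mat riwish(double df, const arma::mat& Psi) {
  int p = Psi.n_rows;
  arma::mat L = arma::chol(arma::inv_sympd(arma::symmatu(Psi)), "lower");
  arma::mat T(p, p, arma::fill::zeros);
  for (int i = 0; i < p; ++i) {
    T(i, i) = std::sqrt(R::rchisq(df - i));
    for (int j = 0; j < i; ++j) T(i, j) = R::norm_rand();
  }
  arma::mat W = L * T;
  W = W * W.t();
  return arma::inv_sympd(arma::symmatu(W));
}

// Univariate animal-model Gibbs sampler.
//
// y = X b + sum_t Z_t u_t + e, u_t ~ N(0, sig2_t * K_t^{-1}) where Kinv[t]
// is the precision kernel of term t (A^{-1} for the additive term, identity
// otherwise), e ~ N(0, sig2_e I). Flat prior on b; scaled-inverse-chi-square
// (nu, V) priors on each variance. Location effects are drawn jointly from
// the mixed-model-equation full conditional.
//
// Returns retained draws of variances, fixed effects and conditional
// deviance, plus the posterior-mean fitted values needed for DIC.
// [[Rcpp::export]]
List gibbs_univariate(const arma::vec& y, const arma::mat& X,
                      const List& Zs, const List& Kinvs,
                      const arma::vec& nu, const arma::vec& V,
                      double nu_e, double V_e,
                      int n_iter, int burnin, int thin,
                      bool prior_only = false) {
  const int n_obs = y.n_elem;
  const int p_f = X.n_cols;
  const int n_terms = Zs.size();

  // assemble W = [X | Z_1 | ... | Z_T]
  std::vector<arma::mat> Z(n_terms);
  std::vector<arma::mat> Kinv(n_terms);
  std::vector<int> q(n_terms), off(n_terms);
  int p = p_f;
  for (int t = 0; t < n_terms; ++t) {
    Z[t] = as<arma::mat>(Zs[t]);
    Kinv[t] = as<arma::mat>(Kinvs[t]);
    q[t] = Z[t].n_cols;
    off[t] = p;
    p += q[t];
  }
  arma::mat W(n_obs, p);
  if (p_f > 0) W.cols(0, p_f - 1) = X;
  for (int t = 0; t < n_terms; ++t)
    W.cols(off[t], off[t] + q[t] - 1) = Z[t];
  arma::mat WtW = W.t() * W;
  arma::vec Wty = W.t() * y;

  int n_keep = (n_iter - burnin) / thin;
  int n_par = n_terms + 1 + p_f + 1; // variances, sig2_e, b, deviance
  arma::mat out(n_keep, n_par);
  arma::vec mean_fitted(n_obs, arma::fill::zeros);
  double mean_sig2e = 0.0, mean_dev = 0.0;
  arma::vec mean_theta(p, arma::fill::zeros);

  // initial values: equal split of the sample variance
  double vy = prior_only ? 1.0 : arma::var(y);
  arma::vec sig2(n_terms);
  sig2.fill(std::max(vy / (n_terms + 1.0), 1e-8));
  double sig2e = std::max(vy / (n_terms + 1.0), 1e-8);
  arma::vec theta(p, arma::fill::zeros);

  int kept = 0;
  for (int it = 1; it <= n_iter; ++it) {
    double dev = NA_REAL;
    if (!prior_only) {
      if (p > 0) {
        arma::mat C = WtW / sig2e;
        for (int t = 0; t < n_terms; ++t)
          C.submat(off[t], off[t], off[t] + q[t] - 1, off[t] + q[t] - 1) +=
            Kinv[t] / sig2[t];
        theta = draw_mvn_canonical(C, Wty / sig2e);
      }
      arma::vec e = (p > 0) ? arma::vec(y - W * theta) : y;
      double sse = arma::dot(e, e);
      sig2e = (sse + nu_e * V_e) / R::rchisq(nu_e + n_obs);
      for (int t = 0; t < n_terms; ++t) {
        arma::vec u = theta.subvec(off[t], off[t] + q[t] - 1);
        double s = arma::as_scalar(u.t() * Kinv[t] * u);
        sig2[t] = (s + nu[t] * V[t]) / R::rchisq(nu[t] + q[t]);
      }
      // conditional deviance at the freshly drawn state
      dev = n_obs * std::log(2.0 * M_PI * sig2e) + sse / sig2e;
    } else {
      sig2e = nu_e * V_e / R::rchisq(nu_e);
      for (int t = 0; t < n_terms; ++t)
        sig2[t] = nu[t] * V[t] / R::rchisq(nu[t]);
    }
    if (it > burnin && (it - burnin) % thin == 0) {
      int k = kept++;
      for (int t = 0; t < n_terms; ++t) out(k, t) = sig2[t];
      out(k, n_terms) = sig2e;
      for (int j = 0; j < p_f; ++j) out(k, n_terms + 1 + j) = theta[j];
      out(k, n_par - 1) = dev;
      if (!prior_only) {
        mean_fitted += W * theta;
        mean_theta += theta;
        mean_sig2e += sig2e;
        mean_dev += dev;
      }
    }
  }
  if (kept > 0 && !prior_only) {
    mean_fitted /= kept;
    mean_theta /= kept;
    mean_sig2e /= kept;
    mean_dev /= kept;
  }
  return List::create(_["samples"] = out,
                      _["mean_fitted"] = mean_fitted,
                      _["mean_theta"] = mean_theta,
                      _["mean_sig2e"] = mean_sig2e,
                      _["mean_deviance"] = mean_dev);
}

// Univariate additive-only fast path: with every phenotyped individual
// carrying one record, rotating by the eigenvectors of A_obs de-correlates
// the breeding values (a_i ~ N(0, d_i sigma2_A) independently), so an
// iteration is O(n) instead of a dense factorization. Inputs are the
// rotated data yt = U'y, Xt = U'X and the eigenvalues d.
// [[Rcpp::export]]
List gibbs_univariate_eigen(const arma::vec& yt, const arma::mat& Xt,
                            const arma::vec& d,
                            double nu_a, double V_a,
                            double nu_e, double V_e,
                            int n_iter, int burnin, int thin) {
  const int n_obs = yt.n_elem;
  const int p_f = Xt.n_cols;
  arma::mat XtX = Xt.t() * Xt;

  int n_keep = (n_iter - burnin) / thin;
  int n_par = 2 + p_f + 1; // VA, VE, b, deviance
  arma::mat out(n_keep, n_par);
  arma::vec mean_fitted(n_obs, arma::fill::zeros);
  double mean_sig2e = 0.0, mean_dev = 0.0;

  double vy = arma::var(yt);
  double sig2a = std::max(vy / 2.0, 1e-8), sig2e = std::max(vy / 2.0, 1e-8);
  arma::vec a(n_obs, arma::fill::zeros), b(p_f, arma::fill::zeros);

  int kept = 0;
  for (int it = 1; it <= n_iter; ++it) {
    if (p_f > 0) {
      arma::mat C = XtX / sig2e;
      arma::vec r = Xt.t() * (yt - a) / sig2e;
      b = draw_mvn_canonical(C, r);
    }
    arma::vec resid = yt - ((p_f > 0) ? arma::vec(Xt * b)
                                      : arma::vec(n_obs, arma::fill::zeros));
    double ssa = 0.0;
    for (int i = 0; i < n_obs; ++i) {
      double prec = 1.0 / sig2e + 1.0 / (d[i] * sig2a);
      double var = 1.0 / prec;
      double mu = var * resid[i] / sig2e;
      a[i] = mu + std::sqrt(var) * R::norm_rand();
      ssa += a[i] * a[i] / d[i];
    }
    sig2a = (ssa + nu_a * V_a) / R::rchisq(nu_a + n_obs);
    arma::vec e = resid - a;
    double sse = arma::dot(e, e);
    sig2e = (sse + nu_e * V_e) / R::rchisq(nu_e + n_obs);
    double dev = n_obs * std::log(2.0 * M_PI * sig2e) + sse / sig2e;

    if (it > burnin && (it - burnin) % thin == 0) {
      int k = kept++;
      out(k, 0) = sig2a;
      out(k, 1) = sig2e;
      for (int j = 0; j < p_f; ++j) out(k, 2 + j) = b[j];
      out(k, n_par - 1) = dev;
      mean_fitted += yt - e;
      mean_sig2e += sig2e;
      mean_dev += dev;
    }
  }
  if (kept > 0) {
    mean_fitted /= kept;
    mean_sig2e /= kept;
    mean_dev /= kept;
  }
  return List::create(_["samples"] = out,
                      _["mean_fitted"] = mean_fitted,
                      _["mean_sig2e"] = mean_sig2e,
                      _["mean_deviance"] = mean_dev);
}

// Bivariate animal model, general mixed-model-equation sampler.
// Y is n_obs x 2 (complete cases); each random term and the residual has an
// unstructured 2x2 covariance with inverse-Wishart(nu, nu*V) prior.
// Location effects are ordered trait-major: theta = [theta_trait1;
// theta_trait2].
// [[Rcpp::export]]
List gibbs_bivariate(const arma::mat& Y, const arma::mat& X,
                     const List& Zs, const List& Kinvs,
                     const arma::vec& nu, const List& Vs,
                     double nu_e, const arma::mat& V_e,
                     int n_iter, int burnin, int thin) {
  const int n_obs = Y.n_rows;
  const int p_f = X.n_cols;
  const int n_terms = Zs.size();

  std::vector<arma::mat> Z(n_terms), Kinv(n_terms), Vp(n_terms);
  std::vector<int> q(n_terms), off(n_terms);
  int p = p_f;
  for (int t = 0; t < n_terms; ++t) {
    Z[t] = as<arma::mat>(Zs[t]);
    Kinv[t] = as<arma::mat>(Kinvs[t]);
    Vp[t] = as<arma::mat>(Vs[t]);
    q[t] = Z[t].n_cols;
    off[t] = p;
    p += q[t];
  }
  arma::mat W(n_obs, p);
  if (p_f > 0) W.cols(0, p_f - 1) = X;
  for (int t = 0; t < n_terms; ++t)
    W.cols(off[t], off[t] + q[t] - 1) = Z[t];
  arma::mat WtW = W.t() * W;
  arma::mat WtY = W.t() * Y; // p x 2

  int n_keep = (n_iter - burnin) / thin;
  // per term: 3 params (v1, cov, v2); residual 3; fixed 2*p_f; deviance
  int n_par = 3 * (n_terms + 1) + 2 * p_f + 1;
  arma::mat out(n_keep, n_par);
  arma::mat mean_fitted(n_obs, 2, arma::fill::zeros);
  arma::mat mean_R(2, 2, arma::fill::zeros);
  double mean_dev = 0.0;

  std::vector<arma::mat> Sig(n_terms);
  arma::vec v0 = {arma::var(Y.col(0)), arma::var(Y.col(1))};
  for (int t = 0; t < n_terms; ++t)
    Sig[t] = arma::diagmat(v0 / (n_terms + 1.0));
  arma::mat Re = arma::diagmat(v0 / (n_terms + 1.0));
  arma::vec theta(2 * p, arma::fill::zeros);

  int kept = 0;
  for (int it = 1; it <= n_iter; ++it) {
    arma::mat Rinv = arma::inv_sympd(arma::symmatu(Re));
    // build 2p x 2p system
    arma::mat C(2 * p, 2 * p, arma::fill::zeros);
    arma::vec r(2 * p);
    for (int s = 0; s < 2; ++s) {
      for (int t2 = 0; t2 < 2; ++t2)
        C.submat(s * p, t2 * p, s * p + p - 1, t2 * p + p - 1) =
          Rinv(s, t2) * WtW;
      r.subvec(s * p, s * p + p - 1) =
        WtY.col(0) * Rinv(s, 0) + WtY.col(1) * Rinv(s, 1);
    }
    for (int t = 0; t < n_terms; ++t) {
      arma::mat Ginv = arma::inv_sympd(arma::symmatu(Sig[t]));
      for (int s = 0; s < 2; ++s)
        for (int t2 = 0; t2 < 2; ++t2)
          C.submat(s * p + off[t], t2 * p + off[t],
                   s * p + off[t] + q[t] - 1, t2 * p + off[t] + q[t] - 1) +=
            Ginv(s, t2) * Kinv[t];
    }
    theta = draw_mvn_canonical(C, r);

    arma::mat Theta(p, 2);
    Theta.col(0) = theta.subvec(0, p - 1);
    Theta.col(1) = theta.subvec(p, 2 * p - 1);
    arma::mat E = Y - W * Theta;
    Re = riwish(nu_e + n_obs, nu_e * V_e + E.t() * E);
    for (int t = 0; t < n_terms; ++t) {
      arma::mat Ut = Theta.rows(off[t], off[t] + q[t] - 1);
      arma::mat S = Ut.t() * Kinv[t] * Ut;
      Sig[t] = riwish(nu[t] + q[t], nu[t] * Vp[t] + S);
    }
    double ldR, sgn;
    arma::log_det(ldR, sgn, Re);
    arma::mat Rinv2 = arma::inv_sympd(arma::symmatu(Re));
    double dev = n_obs * (2.0 * std::log(2.0 * M_PI) + ldR) +
      arma::trace(Rinv2 * (E.t() * E));

    if (it > burnin && (it - burnin) % thin == 0) {
      int k = kept++;
      int c = 0;
      for (int t = 0; t < n_terms; ++t) {
        out(k, c++) = Sig[t](0, 0);
        out(k, c++) = Sig[t](0, 1);
        out(k, c++) = Sig[t](1, 1);
      }
      out(k, c++) = Re(0, 0);
      out(k, c++) = Re(0, 1);
      out(k, c++) = Re(1, 1);
      for (int j = 0; j < p_f; ++j) out(k, c++) = Theta(j, 0);
      for (int j = 0; j < p_f; ++j) out(k, c++) = Theta(j, 1);
      out(k, c) = dev;
      mean_fitted += W * Theta;
      mean_R += Re;
      mean_dev += dev;
    }
  }
  if (kept > 0) {
    mean_fitted /= kept;
    mean_R /= kept;
    mean_dev /= kept;
  }
  return List::create(_["samples"] = out,
                      _["mean_fitted"] = mean_fitted,
                      _["mean_R"] = mean_R,
                      _["mean_deviance"] = mean_dev);
}

// Fast path for the bivariate additive-only model when every phenotyped
// individual carries exactly one record. The relationship matrix of the
// phenotyped set is eigendecomposed once (A = U D U'); rotating the data by
// U' de-correlates the additive effects across individuals, so each a_i has
// an independent 2x2 full conditional and an iteration costs O(n).
// Inputs are the rotated data Yt = U'Y, Xt = U'X and eigenvalues d.
// [[Rcpp::export]]
List gibbs_bivariate_eigen(const arma::mat& Yt, const arma::mat& Xt,
                           const arma::vec& d,
                           double nu_a, const arma::mat& V_a,
                           double nu_e, const arma::mat& V_e,
                           int n_iter, int burnin, int thin) {
  const int n_obs = Yt.n_rows;
  const int p_f = Xt.n_cols;

  arma::mat XtX = Xt.t() * Xt;
  int n_keep = (n_iter - burnin) / thin;
  int n_par = 6 + 2 * p_f + 1;
  arma::mat out(n_keep, n_par);
  double mean_dev = 0.0;
  arma::mat mean_fitted(n_obs, 2, arma::fill::zeros); // rotated scale
  arma::mat mean_R(2, 2, arma::fill::zeros);

  arma::vec v0 = {arma::var(Yt.col(0)), arma::var(Yt.col(1))};
  arma::mat G = arma::diagmat(v0 / 2.0), Re = arma::diagmat(v0 / 2.0);
  arma::mat A(n_obs, 2, arma::fill::zeros); // rotated breeding values
  arma::mat B(p_f, 2, arma::fill::zeros);

  int kept = 0;
  for (int it = 1; it <= n_iter; ++it) {
    arma::mat Rinv = arma::inv_sympd(arma::symmatu(Re));
    arma::mat Ginv = arma::inv_sympd(arma::symmatu(G));

    // fixed effects jointly (trait-major ordering)
    if (p_f > 0) {
      arma::mat Resp = Yt - A; // residual without fixed part
      arma::mat XtResp = Xt.t() * Resp; // p_f x 2
      arma::mat C(2 * p_f, 2 * p_f);
      arma::vec r(2 * p_f);
      for (int s = 0; s < 2; ++s) {
        for (int t2 = 0; t2 < 2; ++t2)
          C.submat(s * p_f, t2 * p_f, s * p_f + p_f - 1, t2 * p_f + p_f - 1) =
            Rinv(s, t2) * XtX;
        r.subvec(s * p_f, s * p_f + p_f - 1) =
          XtResp.col(0) * Rinv(s, 0) + XtResp.col(1) * Rinv(s, 1);
      }
      arma::vec b = draw_mvn_canonical(C, r);
      B.col(0) = b.subvec(0, p_f - 1);
      B.col(1) = b.subvec(p_f, 2 * p_f - 1);
    }

    // breeding values: independent 2x2 conditionals
    arma::mat Resid = Yt - Xt * B; // n x 2, without a
    arma::mat Sa(2, 2, arma::fill::zeros);
    for (int i = 0; i < n_obs; ++i) {
      arma::mat prec = Rinv + Ginv / d[i];
      arma::mat cov = arma::inv_sympd(arma::symmatu(prec));
      arma::vec mu = cov * (Rinv * Resid.row(i).t());
      arma::mat L = arma::chol(cov, "lower");
      arma::vec ai = mu + L * rnorm_vec(2);
      A(i, 0) = ai[0];
      A(i, 1) = ai[1];
      Sa += ai * ai.t() / d[i];
    }
    G = riwish(nu_a + n_obs, nu_a * V_a + Sa);
    arma::mat E = Resid - A;
    Re = riwish(nu_e + n_obs, nu_e * V_e + E.t() * E);

    double ldR, sgn;
    arma::log_det(ldR, sgn, Re);
    arma::mat Rinv2 = arma::inv_sympd(arma::symmatu(Re));
    double dev = n_obs * (2.0 * std::log(2.0 * M_PI) + ldR) +
      arma::trace(Rinv2 * (E.t() * E));

    if (it > burnin && (it - burnin) % thin == 0) {
      int k = kept++;
      int c = 0;
      out(k, c++) = G(0, 0); out(k, c++) = G(0, 1); out(k, c++) = G(1, 1);
      out(k, c++) = Re(0, 0); out(k, c++) = Re(0, 1); out(k, c++) = Re(1, 1);
      for (int j = 0; j < p_f; ++j) out(k, c++) = B(j, 0);
      for (int j = 0; j < p_f; ++j) out(k, c++) = B(j, 1);
      out(k, c) = dev;
      mean_dev += dev;
      mean_fitted += Xt * B + A;
      mean_R += Re;
    }
  }
  if (kept > 0) {
    mean_dev /= kept;
    mean_fitted /= kept;
    mean_R /= kept;
  }
  return List::create(_["samples"] = out, _["mean_deviance"] = mean_dev,
                      _["mean_fitted"] = mean_fitted, _["mean_R"] = mean_R);
}
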