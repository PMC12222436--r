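#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Forward-filter backward-sample for the scalar linear-Gaussian chain
// w_t = u_t + N(0, sigy2), u_t = u_{t-1} + drift_{t-1} + N(0, sigx2),
// u_1 ~ N(m0, s02). Returns one joint draw of u | w.
// [[Rcpp::export]]
NumericVector ffbs_cpp(NumericVector w, NumericVector drift,
                       double sigy2, double sigx2, double m0, double s02) {
  int T = w.size();
  NumericVector m(T), P(T), mp(T), Pp(T), u(T);
  for (int t = 0; t < T; ++t) {
    if (t == 0) { mp[t] = m0; Pp[t] = s02; }
    else { mp[t] = m[t - 1] + drift[t - 1]; Pp[t] = P[t - 1] + sigx2; }
    double S = Pp[t] + sigy2;
    double K = Pp[t] / S;
    m[t] = mp[t] + K * (w[t] - mp[t]);
    P[t] = (1.0 - K) * Pp[t];
  }
  u[T - 1] = R::rnorm(m[T - 1], sqrt(P[T - 1]));
  for (int t = T - 2; t >= 0; --t) {
    double denom = P[t] + sigx2;
    double C = (denom > 0.0) ? P[t] / denom : 0.0;
    double mean = m[t] + C * (u[t + 1] - drift[t] - m[t]);
    double var = (denom > 0.0) ? P[t] * sigx2 / denom : 0.0;
    u[t] = R::rnorm(mean, sqrt(var));
  }
  return u;
}

// inverse-gamma variance draw under a uniform-on-SD prior, truncated at
// sd_max^2 (bound essentially never binds)
static double draw_var_c(double n_obs, double ss, double sd_max) {
  double shape = (n_obs - 1.0) / 2.0;
  for (int r = 0; r < 20; ++r) {
    double v = 1.0 / R::rgamma(shape, 2.0 / ss);  // R::rgamma uses scale
    if (v <= sd_max * sd_max) return v;
  }
  return sd_max * sd_max;
}

// marginal likelihood of w with the latent states integrated out
// (scalar Kalman filter prediction-error decomposition)
static double kf_loglik(const arma::vec& w, const arma::vec& drift,
                        double sigy2, double sigx2, double m0, double s02) {
  int T = w.n_elem;
  double m = 0.0, P = 0.0, ll = 0.0;
  for (int t = 0; t < T; ++t) {
    double mp, Pp;
    if (t == 0) { mp = m0; Pp = s02; }
    else { mp = m + drift(t - 1); Pp = P + sigx2; }
    double S = Pp + sigy2;
    double e = w(t) - mp;
    ll += -0.5 * (log(2.0 * M_PI * S) + e * e / S);
    double K = Pp / S;
    m = mp + K * e;
    P = (1.0 - K) * Pp;
  }
  return ll;
}

// One sweep over all taxa: marginal Metropolis update of the variance
// pair (states integrated out, which decouples the slow sigma_y/sigma_x
// split from the latent chain), FFBS latent log-CPUE redraw, conjugate
// coefficient-block update (beta1..beta3, gamma [, beta4]) and conjugate
// variance updates. Returns the updated blocks.
// [[Rcpp::export]]
List sweep_taxa_cpp(const arma::mat& L, const arma::vec& logz,
                    const List& X, arma::mat u, arma::mat coef,
                    arma::vec beta4, const LogicalVector& restoration,
                    arma::vec sig2y, arma::vec sig2x,
                    const arma::mat& SigInv, const arma::vec& mu,
                    double beta4_sd, double sd_max,
                    const arma::vec& m0, double init_var,
                    bool fix_coef, bool fix_beta4,
                    bool fix_sigy, bool fix_sigx) {
  int n_i = L.n_rows, n_t = L.n_cols;
  for (int i = 0; i < n_i; ++i) {
    const arma::mat& Xi = as<arma::mat>(X[i]);
    int k = Xi.n_cols;
    arma::vec theta(k);
    theta.subvec(0, 3) = coef.row(i).t();
    if (k == 5) theta(4) = beta4(i);
    arma::vec drift = Xi * theta;
    arma::vec w = L.row(i).t() - logz;
    if (!fix_sigy && !fix_sigx) {
      // random-walk MH on (log sd_y, log sd_x); uniform-on-SD prior gives
      // a +log(sd) Jacobian term per component
      double ly = 0.5 * log(sig2y(i)), lx = 0.5 * log(sig2x(i));
      double cur = kf_loglik(w, drift, sig2y(i), sig2x(i), m0(i), init_var) +
        ly + lx;
      for (int rep = 0; rep < 2; ++rep) {
        double ly2 = ly + 0.15 * norm_rand();
        double lx2 = lx + 0.15 * norm_rand();
        if (exp(ly2) >= sd_max || exp(lx2) >= sd_max) continue;
        double prop = kf_loglik(w, drift, exp(2.0 * ly2), exp(2.0 * lx2),
                                m0(i), init_var) + ly2 + lx2;
        if (log(unif_rand()) < prop - cur) {
          ly = ly2; lx = lx2; cur = prop;
        }
      }
      sig2y(i) = exp(2.0 * ly);
      sig2x(i) = exp(2.0 * lx);
    }
    NumericVector ui = ffbs_cpp(wrap(w), wrap(drift), sig2y(i), sig2x(i),
                                m0(i), init_var);
    arma::vec uv = as<arma::vec>(ui);
    u.row(i) = uv.t();
    arma::vec du = arma::diff(uv);
    if (!fix_coef) {
      arma::mat Q0(k, k, arma::fill::zeros);
      Q0.submat(0, 0, 3, 3) = SigInv;
      arma::vec pm(k, arma::fill::zeros);
      pm.subvec(0, 3) = mu;
      if (k == 5) Q0(4, 4) = 1.0 / (beta4_sd * beta4_sd);
      arma::mat Q = Xi.t() * Xi / sig2x(i) + Q0;
      arma::vec rhs = Xi.t() * du / sig2x(i) + Q0 * pm;
      arma::mat Rch = arma::chol(Q);               // upper triangular
      arma::vec mean_th = arma::solve(arma::trimatu(Rch),
                          arma::solve(arma::trimatl(Rch.t()), rhs));
      arma::vec zdraw(k);
      for (int j = 0; j < k; ++j) zdraw(j) = norm_rand();
      theta = mean_th + arma::solve(arma::trimatu(Rch), zdraw);
      coef.row(i) = theta.subvec(0, 3).t();
      if (k == 5 && !fix_beta4) beta4(i) = theta(4);
      else if (k == 5) theta(4) = beta4(i);
    }
    if (!fix_sigy) {
      arma::vec ry = w - uv;
      sig2y(i) = draw_var_c(n_t, arma::dot(ry, ry), sd_max);
    }
    if (!fix_sigx) {
      arma::vec rx = du - Xi * theta;
      sig2x(i) = draw_var_c(n_t - 1, arma::dot(rx, rx), sd_max);
    }
  }
  return List::create(_["u"] = u, _["coef"] = coef, _["beta4"] = beta4,
                      _["sig2y"] = sig2y, _["sig2x"] = sig2x);
}

// Exact draw of a latent effort count at a missing year: zero-truncated
// Poisson(exp(v)) times the lognormal catch likelihood of every taxon,
// sampled by enumeration and inverse-CDF.
// [[Rcpp::export]]
int draw_missing_z_cpp(double v, const arma::vec& logy, const arma::vec& u,
                       const arma::vec& sig2y) {
  double lam = exp(v);
  double prec = arma::accu(1.0 / sig2y);
  double logz_hat = arma::accu((logy - u) / sig2y) / prec;
  double sdz = sqrt(1.0 / prec);
  double lo_d = std::min(lam - 8.0 * sqrt(lam), exp(logz_hat - 8.0 * sdz));
  double hi_d = std::max(lam + 8.0 * sqrt(lam) + 20.0,
                         exp(logz_hat + 8.0 * sdz));
  int lo = std::max(1, (int)floor(lo_d));
  int hi = (int)std::min((double)lo + 5e5, ceil(hi_d));
  int n = hi - lo + 1;
  std::vector<double> lw(n);
  double mx = -INFINITY;
  for (int j = 0; j < n; ++j) {
    double z = lo + j;
    double lz = log(z);
    lw[j] = z * v - lgamma(z + 1.0) -
      0.5 * prec * (lz - logz_hat) * (lz - logz_hat);
    if (lw[j] > mx) mx = lw[j];
  }
  double tot = 0.0;
  for (int j = 0; j < n; ++j) { lw[j] = exp(lw[j] - mx); tot += lw[j]; }
  double target = unif_rand() * tot, cum = 0.0;
  for (int j = 0; j < n; ++j) {
    cum += lw[j];
    if (cum >= target) return lo + j;
  }
  return hi;
}

static double loglambda_target(int t, double v, int T,
                               const NumericVector& vcur,
                               const NumericVector& z,
                               const LogicalVector& trunc,
                               double siglam2, double m0, double s02) {
  // Poisson(z_t | e^v), zero-truncated at latent (missing) years
  double lam = exp(v);
  double lp = z[t] * v - lam;
  if (trunc[t] && lam < 30.0) lp -= log1p(-exp(-lam));
  if (t == 0) {
    lp += -0.5 * (v - m0) * (v - m0) / s02;
  } else {
    double d = v - vcur[t - 1];
    lp += -0.5 * d * d / siglam2;
  }
  if (t < T - 1) {
    double d = vcur[t + 1] - v;
    lp += -0.5 * d * d / siglam2;
  }
  return lp;
}

// One systematic-scan slice-sampling pass over the latent log expected
// effort v = log lambda. Stepping-out slice sampler (Neal 2003).
// [[Rcpp::export]]
NumericVector slice_loglambda_cpp(NumericVector v, NumericVector z,
                                  LogicalVector trunc, double siglam2,
                                  double m0, double s02, double width = 0.3,
                                  int max_steps = 30) {
  int T = v.size();
  NumericVector vnew = clone(v);
  for (int t = 0; t < T; ++t) {
    double x0 = vnew[t];
    double f0 = loglambda_target(t, x0, T, vnew, z, trunc, siglam2, m0, s02);
    double logy = f0 + log(unif_rand());
    double L = x0 - width * unif_rand();
    double Rr = L + width;
    int j = (int)floor(max_steps * unif_rand());
    int k = max_steps - 1 - j;
    while (j > 0 &&
           loglambda_target(t, L, T, vnew, z, trunc, siglam2, m0, s02) > logy) {
      L -= width; --j;
    }
    while (k > 0 &&
           loglambda_target(t, Rr, T, vnew, z, trunc, siglam2, m0, s02) > logy) {
      Rr += width; --k;
    }
    for (;;) {
      double x1 = L + (Rr - L) * unif_rand();
      if (loglambda_target(t, x1, T, vnew, z, trunc, siglam2, m0, s02) > logy) {
        vnew[t] = x1;
        break;
      }
      if (x1 < x0) L = x1; else Rr = x1;
      if (Rr - L < 1e-12) { vnew[t] = x0; break; }
    }
  }
  return vnew;
}
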