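#include <Rcpp.h>
using namespace Rcpp;

// Variance floor applied to posterior variances at levels 2 and 3; keeps the
// sequential filter away from singular precisions for extreme parameters.
static const double VAR_FLOOR = 1e-8;

// One forward pass of the binary Hierarchical Gaussian Filter over a single
// contingency dimension.  `u` is the outcome sequence in contingency space
// (0/1), `relevant[k]` says whether the dimension is task-relevant on trial k
// (selects omega_rel vs omega_irrel).  With `three_level = false` the
// volatility level is frozen at its initial values and kappa is ignored
// (callers pass kappa = 0 for the 2-level model).
//
// Trajectory convention: row k holds the prediction quantities formed before
// outcome k (muhat1, muhat2, pihat2) and the posterior quantities after
// observing outcome k (mu2, sigma2, mu3, sigma3, delta2, eps2, eps3).
// [[Rcpp::export]]
List cpp_hgf_filter(NumericVector u, LogicalVector relevant,
                    double kappa, double omega_rel, double omega_irrel,
                    double theta, double mu2_0, double sigma2_0,
                    double mu3_0, double sigma3_0, bool three_level) {
  int n = u.size();
  NumericVector muhat1(n), delta1(n), muhat2(n), mu2(n), sigma2(n),
      pihat2(n), pi2(n), psi2(n), eps2(n), mu3(n), sigma3(n),
      delta2(n), eps3(n);
  double m2 = mu2_0, s2 = sigma2_0, m3 = mu3_0, s3 = sigma3_0;
  bool ok = true;
  for (int k = 0; k < n; ++k) {
    double uk = u[k];
    if (!(uk == 0.0 || uk == 1.0)) { ok = false; break; }
    double om = relevant[k] ? omega_rel : omega_irrel;
    double mh1 = 1.0 / (1.0 + std::exp(-m2));
    double d1 = uk - mh1;
    // predicted variance of the level-2 random walk for this trial
    double vhat = std::exp(kappa * m3 + om);
    double ph2 = 1.0 / (s2 + vhat);
    double p2 = ph2 + mh1 * (1.0 - mh1);
    double m2new = m2 + d1 / p2;
    double s2new = 1.0 / p2;
    if (s2new < VAR_FLOOR) s2new = VAR_FLOOR;
    // volatility prediction error (value of the level-2 posterior relative
    // to its prediction); computed for both variants for the trajectory
    double d2 = (s2new + (m2new - m2) * (m2new - m2)) * ph2 - 1.0;
    double m3new = m3, s3new = s3, e3 = 0.0;
    if (three_level) {
      double ph3 = 1.0 / (s3 + theta);
      double w2 = vhat * ph2; // relative weight of the walk variance
      double p3 = ph3 +
        0.5 * kappa * kappa * w2 * (w2 + (2.0 * w2 - 1.0) * d2);
      if (!(p3 > 0.0)) { ok = false; break; }
      m3new = m3 + 0.5 * kappa * (w2 / p3) * d2;
      s3new = 1.0 / p3;
      if (s3new < VAR_FLOOR) s3new = VAR_FLOOR;
      e3 = m3new - m3;
    }
    muhat1[k] = mh1; delta1[k] = d1; muhat2[k] = m2;
    pihat2[k] = ph2; pi2[k] = p2; psi2[k] = 1.0 / p2;
    eps2[k] = d1 / p2; mu2[k] = m2new; sigma2[k] = s2new;
    mu3[k] = m3new; sigma3[k] = s3new; delta2[k] = d2; eps3[k] = e3;
    if (!std::isfinite(m2new) || !std::isfinite(m3new)) { ok = false; break; }
    m2 = m2new; s2 = s2new; m3 = m3new; s3 = s3new;
  }
  return List::create(
    _["muhat1"] = muhat1, _["delta1"] = delta1, _["muhat2"] = muhat2,
    _["mu2"] = mu2, _["sigma2"] = sigma2, _["pihat2"] = pihat2,
    _["pi2"] = pi2, _["psi2"] = psi2, _["eps2"] = eps2,
    _["mu3"] = mu3, _["sigma3"] = sigma3, _["delta2"] = delta2,
    _["eps3"] = eps3, _["ok"] = ok);
}

// Fast path used inside the optimizer: returns only the trial-wise outcome
// predictions muhat1, or a length-1 NaN vector if the filter hit a
// numerical pathology (treated as -Inf log-likelihood upstream).
// [[Rcpp::export]]
NumericVector cpp_hgf_muhat1(NumericVector u, LogicalVector relevant,
                             double kappa, double omega_rel,
                             double omega_irrel, double theta,
                             double mu2_0, double sigma2_0,
                             double mu3_0, double sigma3_0,
                             bool three_level) {
  int n = u.size();
  NumericVector muhat1(n);
  double m2 = mu2_0, s2 = sigma2_0, m3 = mu3_0, s3 = sigma3_0;
  for (int k = 0; k < n; ++k) {
    double uk = u[k];
    double om = relevant[k] ? omega_rel : omega_irrel;
    double mh1 = 1.0 / (1.0 + std::exp(-m2));
    muhat1[k] = mh1;
    double d1 = uk - mh1;
    double vhat = std::exp(kappa * m3 + om);
    double ph2 = 1.0 / (s2 + vhat);
    double p2 = ph2 + mh1 * (1.0 - mh1);
    double m2new = m2 + d1 / p2;
    double s2new = 1.0 / p2;
    if (s2new < VAR_FLOOR) s2new = VAR_FLOOR;
    if (three_level) {
      double d2 = (s2new + (m2new - m2) * (m2new - m2)) * ph2 - 1.0;
      double ph3 = 1.0 / (s3 + theta);
      double w2 = vhat * ph2;
      double p3 = ph3 +
        0.5 * kappa * kappa * w2 * (w2 + (2.0 * w2 - 1.0) * d2);
      if (!(p3 > 0.0)) return NumericVector::create(NA_REAL);
      m3 = m3 + 0.5 * kappa * (w2 / p3) * d2;
      s3 = 1.0 / p3;
      if (s3 < VAR_FLOOR) s3 = VAR_FLOOR;
    }
    if (!std::isfinite(m2new) || !std::isfinite(m3))
      return NumericVector::create(NA_REAL);
    m2 = m2new; s2 = s2new;
  }
  return muhat1;
}

// Rescorla-Wagner value recursion; returns the pre-outcome prediction v(k).
// [[Rcpp::export]]
NumericVector cpp_rw_muhat1(NumericVector u, double alpha, double v0) {
  int n = u.size();
  NumericVector muhat1(n);
  double v = v0;
  for (int k = 0; k < n; ++k) {
    muhat1[k] = v;
    v = v + alpha * (u[k] - v);
  }
  return muhat1;
}

// Negative log-likelihood of the relevance-weighted logistic response model.
// `y` is the scored response for the trial's current task in contingency
// space (NA = no response, contributes zero).  On spatial-task trials the
// relevant prediction is muhat1_s (weight zeta_s_rel) and the irrelevant one
// muhat1_t (weight zeta_t_irrel); vice versa on temporal-task trials.
// `sign` is +1 for the congruent-response convention, -1 for the literal
// printed form of the softmax.
// [[Rcpp::export]]
double cpp_response_negll(NumericVector muhat1_s, NumericVector muhat1_t,
                          NumericVector y, LogicalVector task_spatial,
                          double zeta_s_rel, double zeta_t_rel,
                          double zeta_s_irrel, double zeta_t_irrel,
                          double sign) {
  int n = y.size();
  if (muhat1_s.size() != n || muhat1_t.size() != n)
    stop("trajectory/trial length mismatch");
  double nll = 0.0;
  for (int k = 0; k < n; ++k) {
    if (NumericVector::is_na(y[k])) continue;
    double ms = 2.0 * muhat1_s[k] - 1.0;
    double mt = 2.0 * muhat1_t[k] - 1.0;
    double x;
    if (task_spatial[k]) {
      x = zeta_s_rel * ms + zeta_t_irrel * mt;
    } else {
      x = zeta_t_rel * mt + zeta_s_irrel * ms;
    }
    double z = sign * x * (2.0 * y[k] - 1.0);
    // -log(s(z)) = log(1 + exp(-z)), computed stably
    nll += (z > 0.0) ? std::log1p(std::exp(-z))
                     : (-z + std::log1p(std::exp(z)));
  }
  return nll;
}
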