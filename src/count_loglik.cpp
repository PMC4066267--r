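// Marginal log-likelihood kernels for subject-random-intercept count models:
// Poisson (PLME), negative binomial (NBLME) and zero-inflated negative
// binomial (ZINBLME).  The random intercept enters the (NB/Poisson) mean
// linear predictor only; the zero-inflation component is intercept-only.
// The per-subject integral over the random effect is evaluated by adaptive
// Gauss-Hermite quadrature centred on the per-subject posterior mode.
//
// Parameter vector (transformed, unconstrained):
//   theta = c(beta[1..p], log_sigma_b, [log_k], [logit_pi])
// Family codes: 0 = Poisson, 1 = NB, 2 = ZINB.

#include <Rcpp.h>
using namespace Rcpp;

static const double ETA_CAP = 30.0;

struct FamPars {
  int family;
  double k;      // NB size (ignored for Poisson)
  double pi;     // zero-inflation probability (ZINB only)
  double log1mpi;
};

// log f(y | b) for one observation with linear predictor eta (already + b)
static inline double obs_loglik(int y, double eta, const FamPars& fp) {
  if (eta > ETA_CAP) eta = ETA_CAP;
  if (eta < -ETA_CAP) eta = -ETA_CAP;
  double mu = std::exp(eta);
  if (fp.family == 0) {
    return y * eta - mu - R::lgammafn(y + 1.0);
  }
  double k = fp.k;
  double lognb;
  if (y == 0) {
    lognb = -k * std::log1p(mu / k);
  } else {
    lognb = R::lgammafn(y + k) - R::lgammafn(k) - R::lgammafn(y + 1.0)
      + k * std::log(k) + y * eta - (y + k) * std::log(k + mu);
  }
  if (fp.family == 1) return lognb;
  // ZINB
  if (y == 0) {
    // log(pi + (1-pi) * exp(lognb)), both terms in (0,1]
    double a = fp.pi, bterm = std::exp(fp.log1mpi + lognb);
    return std::log(a + bterm);
  }
  return fp.log1mpi + lognb;
}

// first/second derivative in b of log f(y | b)
static inline void obs_d12(int y, double eta, const FamPars& fp,
                           double& d1, double& d2) {
  if (eta > ETA_CAP) eta = ETA_CAP;
  if (eta < -ETA_CAP) eta = -ETA_CAP;
  double mu = std::exp(eta);
  if (fp.family == 0) {
    d1 = y - mu; d2 = -mu; return;
  }
  double k = fp.k;
  if (fp.family == 1 || y > 0) {
    d1 = y - (y + k) * mu / (k + mu);
    d2 = -(y + k) * k * mu / ((k + mu) * (k + mu));
    return;
  }
  // ZINB, y == 0
  double log_g0 = -k * std::log1p(mu / k);
  double g0 = std::exp(log_g0);
  double onemp = std::exp(fp.log1mpi);
  double f0 = fp.pi + onemp * g0;
  double A = onemp * g0 / f0;                   // in (0, 1]
  double u = -k * mu / (k + mu);                // d log g0 / d b
  double dudb = -k * k * mu / ((k + mu) * (k + mu));
  d1 = A * u;
  d2 = A * (1.0 - A) * u * u + A * dudb;
}

// gradient of log f(y | b) w.r.t. (eta, log_k, logit_pi)
static inline void obs_grad(int y, double eta, const FamPars& fp,
                            double& g_eta, double& g_logk, double& g_zeta) {
  if (eta > ETA_CAP) eta = ETA_CAP;
  if (eta < -ETA_CAP) eta = -ETA_CAP;
  double mu = std::exp(eta);
  g_logk = 0.0; g_zeta = 0.0;
  if (fp.family == 0) { g_eta = y - mu; return; }
  double k = fp.k;
  if (fp.family == 1 || y > 0) {
    g_eta = y - (y + k) * mu / (k + mu);
    g_logk = k * (R::digamma(y + k) - R::digamma(k) + std::log(k) + 1.0
                  - std::log(k + mu) - (y + k) / (k + mu));
    if (fp.family == 2) g_zeta = -fp.pi;
    return;
  }
  // ZINB, y == 0
  double log_g0 = -k * std::log1p(mu / k);
  double g0 = std::exp(log_g0);
  double onemp = std::exp(fp.log1mpi);
  double f0 = fp.pi + onemp * g0;
  double A = onemp * g0 / f0;
  double u = -k * mu / (k + mu);                       // dlog g0/db (= d/deta)
  double v = k * (std::log(k / (k + mu)) + 1.0 - k / (k + mu)); // dlog g0/dlog k
  g_eta = A * u;
  g_logk = A * v;
  // d log(pi + (1-pi) g0) / d zeta, with dpi/dzeta = pi(1-pi)
  g_zeta = fp.pi * (1.0 - fp.pi) * (1.0 - g0) / f0;
}

// [[Rcpp::export]]
List agh_marginal_cpp(NumericVector theta, IntegerVector y, NumericMatrix X,
                      NumericVector offset, IntegerVector subj_start,
                      int family, NumericVector gh_z, NumericVector gh_w,
                      bool want_grad) {
  const int n = y.size(), p = X.ncol(), nq = gh_z.size();
  const int S = subj_start.size() - 1;
  int npar = p + 1 + (family >= 1 ? 1 : 0) + (family == 2 ? 1 : 0);
  if (theta.size() != npar) stop("parameter vector has wrong length");

  FamPars fp; fp.family = family; fp.k = 1.0; fp.pi = 0.0; fp.log1mpi = 0.0;
  double log_sigma = theta[p];
  double sigma = std::exp(log_sigma);
  if (family >= 1) fp.k = std::exp(theta[p + 1]);
  if (family == 2) {
    double zeta = theta[p + 2];
    fp.pi = 1.0 / (1.0 + std::exp(-zeta));
    fp.log1mpi = -std::log1p(std::exp(zeta));
  }
  double sig2 = sigma * sigma;

  // base linear predictor
  std::vector<double> eta0(n);
  for (int i = 0; i < n; ++i) {
    double e = offset[i];
    for (int j = 0; j < p; ++j) e += X(i, j) * theta[j];
    eta0[i] = e;
  }

  double loglik = 0.0;
  NumericVector grad(npar);
  std::vector<double> hval(nq), pw(nq);

  for (int s = 0; s < S; ++s) {
    int i0 = subj_start[s], i1 = subj_start[s + 1];

    // Newton search for the mode of h(b) = sum_j log f(y_j|b) + log phi(b;0,sig2)
    double b = 0.0, d1 = 0.0, d2 = -1.0;
    for (int it = 0; it < 60; ++it) {
      d1 = -b / sig2; d2 = -1.0 / sig2;
      for (int i = i0; i < i1; ++i) {
        double o1, o2; obs_d12(y[i], eta0[i] + b, fp, o1, o2);
        d1 += o1; d2 += o2;
      }
      if (std::fabs(d1) < 1e-9 * (1.0 + std::fabs(b))) break;
      double step = (d2 < -1e-12) ? (-d1 / d2) : d1 * sig2;
      if (step > 5.0) step = 5.0;
      if (step < -5.0) step = -5.0;
      // backtracking on h
      double h_old = -0.5 * b * b / sig2;
      for (int i = i0; i < i1; ++i) h_old += obs_loglik(y[i], eta0[i] + b, fp);
      double bnew = b, h_new = h_old;
      double lam = 1.0;
      for (int half = 0; half < 20; ++half) {
        bnew = b + lam * step;
        h_new = -0.5 * bnew * bnew / sig2;
        for (int i = i0; i < i1; ++i) h_new += obs_loglik(y[i], eta0[i] + bnew, fp);
        if (h_new >= h_old - 1e-12) break;
        lam *= 0.5;
      }
      if (std::fabs(bnew - b) < 1e-10) { b = bnew; break; }
      b = bnew;
    }
    // curvature at the mode
    d2 = -1.0 / sig2;
    for (int i = i0; i < i1; ++i) {
      double o1, o2; obs_d12(y[i], eta0[i] + b, fp, o1, o2);
      d2 += o2;
    }
    double tau = (d2 < -1e-12) ? 1.0 / std::sqrt(-d2) : sigma;

    // adaptive quadrature: b_i = bhat + sqrt(2) tau z_i
    double m = -INFINITY;
    for (int q = 0; q < nq; ++q) {
      double bq = b + M_SQRT2 * tau * gh_z[q];
      double hq = -0.5 * bq * bq / sig2 - log_sigma - 0.5 * std::log(2.0 * M_PI);
      for (int i = i0; i < i1; ++i) hq += obs_loglik(y[i], eta0[i] + bq, fp);
      hval[q] = std::log(gh_w[q]) + gh_z[q] * gh_z[q] + hq;
      if (hval[q] > m) m = hval[q];
    }
    if (!R_finite(m)) return List::create(_["loglik"] = R_NegInf,
                                          _["grad"] = grad,
                                          _["bad_subject"] = s + 1);
    double tot = 0.0;
    for (int q = 0; q < nq; ++q) { pw[q] = std::exp(hval[q] - m); tot += pw[q]; }
    double Ls = std::log(tot) + m + 0.5 * std::log(2.0) + std::log(tau);
    loglik += Ls;

    if (want_grad) {
      for (int q = 0; q < nq; ++q) {
        double w = pw[q] / tot;
        if (w < 1e-14) continue;
        double bq = b + M_SQRT2 * tau * gh_z[q];
        double gsig = bq * bq / sig2 - 1.0;  // d log phi / d log sigma
        double sum_logk = 0.0, sum_zeta = 0.0;
        for (int i = i0; i < i1; ++i) {
          double ge, gk, gz;
          obs_grad(y[i], eta0[i] + bq, fp, ge, gk, gz);
          for (int j = 0; j < p; ++j) grad[j] += w * ge * X(i, j);
          sum_logk += gk; sum_zeta += gz;
        }
        grad[p] += w * gsig;
        if (family >= 1) grad[p + 1] += w * sum_logk;
        if (family == 2) grad[p + 2] += w * sum_zeta;
      }
    }
  }

  return List::create(_["loglik"] = loglik, _["grad"] = grad,
                      _["bad_subject"] = -1);
}

// Conditional (sigma_b = 0) log-likelihood: sum of independent log pmfs.
// [[Rcpp::export]]
double cond_loglik_cpp(NumericVector beta, IntegerVector y, NumericMatrix X,
                       NumericVector offset, int family,
                       double k, double pi) {
  const int n = y.size(), p = X.ncol();
  FamPars fp; fp.family = family; fp.k = k; fp.pi = pi;
  fp.log1mpi = std::log1p(-pi);
  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    double e = offset[i];
    for (int j = 0; j < p; ++j) e += X(i, j) * beta[j];
    ll += obs_loglik(y[i], e, fp);
  }
  return ll;
}
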