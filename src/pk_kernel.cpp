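#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Two-compartment disposition with zero-order (infusion) input, solved in
// closed form per infusion event and superposed (the system is linear and
// time-invariant).  Micro-rate constants: k10 = CL/Vc, k12 = Q/Vc,
// k21 = Q/Vp.  The 2x2 rate matrix has two real eigenvalues l1 >= l2; the
// discriminant (k10+k12-k21)^2 + 4*k12*k21 is non-negative, so no complex
// arithmetic is ever needed.  phi(l, t) = (exp(l*t)-1)/l extends the matrix
// exponential integral to a zero eigenvalue (Q = 0 limit).

static inline double phi_fun(double l, double t) {
  if (std::fabs(l * t) < 1e-12) return t * (1.0 + 0.5 * l * t);
  return std::expm1(l * t) / l;
}

struct TwoCmt {
  double k10, k12, k21, a11, l1, l2, Vc;
  void init(double CL, double Vc_, double Vp, double Q) {
    Vc  = Vc_;
    k10 = CL / Vc;
    k12 = Q / Vc;
    k21 = Q / Vp;
    a11 = -(k10 + k12);
    double s = k10 + k12 + k21;
    double disc = s * s - 4.0 * k10 * k21;
    if (disc < 0.0) disc = 0.0;
    double r = std::sqrt(disc);
    // guard against a (measure-zero) repeated root: split the eigenvalues
    // by a relative nudge; error is O(1e-10) in the profile
    if (r < 1e-10 * s) r = 1e-10 * s + 1e-300;
    l1 = 0.5 * (-s + r);
    l2 = 0.5 * (-s - r);
  }
  // central-compartment concentration at time t from one infusion event
  // (start ts, duration d, rate R), starting from an empty system
  double conc_event(double R, double ts, double d, double t) const {
    double te = t - ts;
    if (te <= 0.0 || R == 0.0) return 0.0;
    double tin = te < d ? te : d;
    double den = l1 - l2;
    double p1 = phi_fun(l1, tin), p2 = phi_fun(l2, tin);
    double A1 = R * ((l1 + k21) * p1 - (l2 + k21) * p2) / den;
    if (te <= d) return A1 / Vc;
    double A2 = R * k12 * (p1 - p2) / den;
    double tau = te - d;
    double c1 = (a11 - l2) * A1 + k21 * A2;  // ((A - l2 I) x)_1
    double c2 = (a11 - l1) * A1 + k21 * A2;  // ((A - l1 I) x)_1
    double out = (std::exp(l1 * tau) * c1 - std::exp(l2 * tau) * c2) / den;
    return out / Vc;
  }
  double conc(const NumericMatrix& ev, double t) const {
    double c = 0.0;
    for (int i = 0; i < ev.nrow(); ++i) {
      double d = ev(i, 1);
      double R = ev(i, 2) / d;
      c += conc_event(R, ev(i, 0), d, t);
    }
    return c < 0.0 ? 0.0 : c;  // clip tiny negative round-off
  }
};

// [[Rcpp::export(name = ".cpp_profile")]]
NumericVector cpp_profile(NumericVector theta, NumericMatrix events,
                          NumericVector times) {
  TwoCmt m;
  m.init(theta[0], theta[1], theta[2], theta[3]);
  int n = times.size();
  NumericVector out(n);
  for (int j = 0; j < n; ++j) out[j] = m.conc(events, times[j]);
  return out;
}

// profiles for many parameter draws on a common grid (Monte Carlo PTA)
// [[Rcpp::export(name = ".cpp_profile_matrix")]]
NumericMatrix cpp_profile_matrix(NumericMatrix theta, NumericMatrix events,
                                 NumericVector times) {
  int n = theta.nrow(), T = times.size();
  NumericMatrix out(n, T);
  for (int i = 0; i < n; ++i) {
    TwoCmt m;
    m.init(theta(i, 0), theta(i, 1), theta(i, 2), theta(i, 3));
    for (int j = 0; j < T; ++j) out(i, j) = m.conc(events, times[j]);
  }
  return out;
}

// joint -2 log density of one subject's observations and random effects.
// tv: typical (covariate-adjusted) CL, Vc, Vp, Q for this subject.
// omega2: BSV variances for (CL, Vc, Vp); entries > 0 carry an eta, in that
// order, so eta.size() == number of positive omega2 entries.
// err_model: 0 exponential (exact, on the log scale), 1 additive,
// 2 combined (variance sigma[0] + sigma[1]*f^2 on the natural scale).
static double joint_g(const double* tv, const NumericMatrix& events,
                      const NumericVector& tobs, const NumericVector& y,
                      const double* eta, const NumericVector& omega2,
                      const NumericVector& sigma2, int err_model,
                      bool* bad_pred) {
  double par[4] = {tv[0], tv[1], tv[2], tv[3]};
  int pos = 0;
  for (int k = 0; k < 3; ++k)
    if (omega2[k] > 0.0) par[k] *= std::exp(eta[pos++]);
  TwoCmt m;
  m.init(par[0], par[1], par[2], par[3]);
  const double LOG2PI = 1.8378770664093453;
  double g = 0.0;
  for (int j = 0; j < tobs.size(); ++j) {
    double f = m.conc(events, tobs[j]);
    if (err_model == 0) {
      if (f <= 0.0) { if (bad_pred) *bad_pred = true; return R_PosInf; }
      double r = std::log(y[j]) - std::log(f);
      g += LOG2PI + std::log(sigma2[0]) + r * r / sigma2[0];
    } else {
      double v = (err_model == 1) ? sigma2[0] : sigma2[0] + sigma2[1] * f * f;
      double r = y[j] - f;
      g += LOG2PI + std::log(v) + r * r / v;
    }
  }
  pos = 0;
  for (int k = 0; k < 3; ++k)
    if (omega2[k] > 0.0) {
      double e = eta[pos++];
      g += LOG2PI + std::log(omega2[k]) + e * e / omega2[k];
    }
  return g;
}

// [[Rcpp::export(name = ".cpp_joint_g")]]
double cpp_joint_g(NumericVector tv, NumericMatrix events, NumericVector tobs,
                   NumericVector y, NumericVector eta, NumericVector omega2,
                   NumericVector sigma2, int err_model) {
  bool bad = false;
  double g = joint_g(REAL(tv), events, tobs, y,
                     eta.size() ? REAL(eta) : nullptr,
                     omega2, sigma2, err_model, &bad);
  if (bad) return R_PosInf;
  return g;
}

static void fd_grad_hess(const double* tv, const NumericMatrix& events,
                         const NumericVector& tobs, const NumericVector& y,
                         double* eta, int q, const NumericVector& omega2,
                         const NumericVector& sigma2, int err_model,
                         double* grad, double* H) {
  const double h = 1e-4;
  double g0 = joint_g(tv, events, tobs, y, eta, omega2, sigma2, err_model,
                      nullptr);
  double gp[3], gm[3];
  for (int k = 0; k < q; ++k) {
    double e0 = eta[k];
    eta[k] = e0 + h;
    gp[k] = joint_g(tv, events, tobs, y, eta, omega2, sigma2, err_model,
                    nullptr);
    eta[k] = e0 - h;
    gm[k] = joint_g(tv, events, tobs, y, eta, omega2, sigma2, err_model,
                    nullptr);
    eta[k] = e0;
    grad[k] = (gp[k] - gm[k]) / (2.0 * h);
    H[k * q + k] = (gp[k] + gm[k] - 2.0 * g0) / (h * h);
  }
  for (int k = 0; k < q; ++k)
    for (int l = k + 1; l < q; ++l) {
      double ek = eta[k], el = eta[l];
      eta[k] = ek + h; eta[l] = el + h;
      double gpp = joint_g(tv, events, tobs, y, eta, omega2, sigma2,
                           err_model, nullptr);
      eta[l] = el - h;
      double gpm = joint_g(tv, events, tobs, y, eta, omega2, sigma2,
                           err_model, nullptr);
      eta[k] = ek - h;
      double gmm = joint_g(tv, events, tobs, y, eta, omega2, sigma2,
                           err_model, nullptr);
      eta[l] = el + h;
      double gmp = joint_g(tv, events, tobs, y, eta, omega2, sigma2,
                           err_model, nullptr);
      eta[k] = ek; eta[l] = el;
      double v = (gpp - gpm - gmp + gmm) / (4.0 * h * h);
      H[k * q + l] = v;
      H[l * q + k] = v;
    }
}

static bool solve_sym(int q, const double* H, const double* b, double* x,
                      double ridge) {
  // tiny dense solve (q <= 3) via Cholesky with optional ridge
  double A[9];
  for (int i = 0; i < q * q; ++i) A[i] = H[i];
  for (int i = 0; i < q; ++i) A[i * q + i] += ridge;
  double L[9] = {0};
  for (int i = 0; i < q; ++i) {
    for (int j = 0; j <= i; ++j) {
      double s = A[i * q + j];
      for (int k = 0; k < j; ++k) s -= L[i * q + k] * L[j * q + k];
      if (i == j) {
        if (s <= 0.0) return false;
        L[i * q + i] = std::sqrt(s);
      } else L[i * q + j] = s / L[j * q + j];
    }
  }
  double zwork[3];
  for (int i = 0; i < q; ++i) {
    double s = b[i];
    for (int k = 0; k < i; ++k) s -= L[i * q + k] * zwork[k];
    zwork[i] = s / L[i * q + i];
  }
  for (int i = q - 1; i >= 0; --i) {
    double s = zwork[i];
    for (int k = i + 1; k < q; ++k) s -= L[k * q + i] * x[k];
    x[i] = s / L[i * q + i];
  }
  return true;
}

static double logdet_sym(int q, const double* H, bool* ok) {
  double L[9] = {0};
  double A[9];
  for (int i = 0; i < q * q; ++i) A[i] = H[i];
  double ld = 0.0;
  for (int i = 0; i < q; ++i) {
    for (int j = 0; j <= i; ++j) {
      double s = A[i * q + j];
      for (int k = 0; k < j; ++k) s -= L[i * q + k] * L[j * q + k];
      if (i == j) {
        if (s <= 0.0) { *ok = false; return 0.0; }
        L[i * q + i] = std::sqrt(s);
        ld += 2.0 * std::log(L[i * q + i]);
      } else L[i * q + j] = s / L[j * q + j];
    }
  }
  *ok = true;
  return ld;
}

// Inner step of the Laplace approximation for one subject: Newton search for
// the posterior mode of eta (damped, finite-difference derivatives), then
// -2 log of the Laplace-approximated marginal likelihood,
//   g(eta_hat) - q*log(2*pi) + log det( H_g(eta_hat) / 2 ).
// [[Rcpp::export(name = ".cpp_laplace_subject")]]
List cpp_laplace_subject(NumericVector tv, NumericMatrix events,
                         NumericVector tobs, NumericVector y,
                         NumericVector omega2, NumericVector sigma2,
                         int err_model, NumericVector eta_start,
                         double grad_tol = 1e-8, int max_iter = 50) {
  int q = 0;
  for (int k = 0; k < 3; ++k) if (omega2[k] > 0.0) ++q;
  const double LOG2PI = 1.8378770664093453;
  bool bad = false;
  if (q == 0) {
    double g = joint_g(REAL(tv), events, tobs, y, nullptr, omega2, sigma2,
                       err_model, &bad);
    return List::create(_["ofv"] = g, _["eta"] = NumericVector(0),
                        _["g"] = g, _["converged"] = !bad,
                        _["iterations"] = 0);
  }
  double eta[3] = {0, 0, 0};
  for (int k = 0; k < q && k < eta_start.size(); ++k) eta[k] = eta_start[k];
  double g = joint_g(REAL(tv), events, tobs, y, eta, omega2, sigma2,
                     err_model, &bad);
  if (!R_finite(g)) { eta[0] = eta[1] = eta[2] = 0.0;
    g = joint_g(REAL(tv), events, tobs, y, eta, omega2, sigma2, err_model,
                &bad); }
  double grad[3], H[9], step[3];
  bool converged = false;
  int it = 0;
  for (; it < max_iter; ++it) {
    fd_grad_hess(REAL(tv), events, tobs, y, eta, q, omega2, sigma2,
                 err_model, grad, H);
    double gmax = 0.0;
    for (int k = 0; k < q; ++k) gmax = std::max(gmax, std::fabs(grad[k]));
    if (gmax < grad_tol) { converged = true; break; }
    double ridge = 0.0;
    while (!solve_sym(q, H, grad, step, ridge))
      ridge = (ridge == 0.0) ? 1e-6 : ridge * 10.0;
    double lambda = 1.0;
    double gnew = R_PosInf;
    double trial[3];
    for (int ls = 0; ls < 30; ++ls) {
      for (int k = 0; k < q; ++k) trial[k] = eta[k] - lambda * step[k];
      gnew = joint_g(REAL(tv), events, tobs, y, trial, omega2, sigma2,
                     err_model, nullptr);
      if (R_finite(gnew) && gnew <= g + 1e-12) break;
      lambda *= 0.5;
    }
    if (!R_finite(gnew) || gnew > g) break;  // stalled
    double move = 0.0;
    for (int k = 0; k < q; ++k) {
      move = std::max(move, std::fabs(eta[k] - trial[k]));
      eta[k] = trial[k];
    }
    if (g - gnew < 1e-12 && move < 1e-10) { g = gnew; converged = true;
      break; }
    g = gnew;
  }
  fd_grad_hess(REAL(tv), events, tobs, y, eta, q, omega2, sigma2, err_model,
               grad, H);
  bool ok = false;
  double ld = logdet_sym(q, H, &ok);
  if (!ok) {  // fall back: ridge until PD (prior curvature guarantees > 0)
    double ridge = 1e-8;
    double Hr[9];
    while (!ok && ridge < 1e8) {
      for (int i = 0; i < q * q; ++i) Hr[i] = H[i];
      for (int i = 0; i < q; ++i) Hr[i * q + i] += ridge;
      ld = logdet_sym(q, Hr, &ok);
      ridge *= 10.0;
    }
  }
  double ofv = g - q * LOG2PI + ld - q * std::log(2.0);
  NumericVector eta_out(q);
  for (int k = 0; k < q; ++k) eta_out[k] = eta[k];
  return List::create(_["ofv"] = ofv, _["eta"] = eta_out, _["g"] = g,
                      _["converged"] = converged, _["iterations"] = it);
}
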