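// Steady-state solver for the single-mode non-Gaussian Rolie-Poly model
// under homogeneous simple shear, u = (gamma_dot * y, 0, 0).
//
// Unknowns are the deviations from equilibrium B = A - I, reduced to
// (Bxx, Bxy, Byy) with Azz = Ayy (the yy and zz equations coincide for
// planar shear; the R layer verifies rather than assumes this).  Working
// in B avoids catastrophic cancellation in the linear regime, where
// Bxy ~ tauD*gd and Bxx - Byy ~ 2*(tauD*gd)^2 can sit 12 decades below 1.
//
// Steady equations (residual form), with e = trA - 3 = Bxx + 2*Byy:
//   R1 = 2*gd*Bxy - Bxx/tauD - st*(1 + (1+b)*Bxx)          [xx]
//   R2 = gd*(1+Byy) - Bxy/tauD - st*(1+b)*Bxy              [xy]
//   R3 = -Byy/tauD - st*(1 + (1+b)*Byy)                    [yy]
// where st = (2/tauR)*ks(lambda)*(1-sqrt(3/trA)), b = beta*(trA/3)^delta,
// and ks is the FENE spring factor.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct RPConst {
  double tau_D, tau_R, chi2, beta, delta;
};

struct Terms {
  double st, dst;   // stretch-relaxation scalar and d/de
  double b, db;     // CCR factor and d/de
  double ks, dks;   // spring factor and d/de
  double lam2;      // trA/3
};

// e = trA - 3; all derivatives are w.r.t. e
inline bool eval_terms(const double* u, const RPConst& c, Terms& t) {
  const double e = u[0] + 2.0 * u[2];
  const double T = 3.0 + e;
  if (T <= 0.0) return false;
  const double lam2 = T / 3.0;
  if (lam2 >= c.chi2 * (1.0 - 1e-9)) return false;  // finite extensibility
  const double r  = lam2 / c.chi2;
  const double C1 = 1.0 - 1.0 / c.chi2;
  const double C2 = 3.0 - 1.0 / c.chi2;
  const double N  = (3.0 - r) * C1;
  const double Dn = (1.0 - r) * C2;
  const double ks = N / Dn;
  const double dks_dr = (-C1 * Dn + N * C2) / (Dn * Dn);
  const double dks = dks_dr / (3.0 * c.chi2);
  // 1 - sqrt(3/T) = e / (T + sqrt(3 T)), stable for small e
  const double sT  = std::sqrt(T);
  const double den = T + std::sqrt(3.0) * sT;
  const double h   = e / den;
  const double dden = 1.0 + std::sqrt(3.0) / (2.0 * sT);
  const double dh  = (den - e * dden) / (den * den);
  const double st  = (2.0 / c.tau_R) * ks * h;
  const double dst = (2.0 / c.tau_R) * (dks * h + ks * dh);
  const double b  = c.beta * std::pow(lam2, c.delta);
  const double db = c.beta * c.delta * std::pow(lam2, c.delta - 1.0) / 3.0;
  t.st = st; t.dst = dst; t.b = b; t.db = db; t.ks = ks; t.dks = dks;
  t.lam2 = lam2;
  return true;
}

inline void residual(const double* u, double gd, const RPConst& c,
                     const Terms& t, double* R) {
  const double Bxx = u[0], Bxy = u[1], Byy = u[2];
  const double P1 = 1.0 + Bxx + t.b * Bxx;   // [A + b (A - I)]_xx
  const double P3 = 1.0 + Byy + t.b * Byy;   // [A + b (A - I)]_yy
  R[0] = 2.0 * gd * Bxy - Bxx / c.tau_D - t.st * P1;
  R[1] = gd * (1.0 + Byy) - Bxy / c.tau_D - t.st * (1.0 + t.b) * Bxy;
  R[2] = -Byy / c.tau_D - t.st * P3;
}

inline void jacobian(const double* u, double gd, const RPConst& c,
                     const Terms& t, double J[3][3]) {
  const double Bxx = u[0], Bxy = u[1], Byy = u[2];
  const double P1 = 1.0 + Bxx + t.b * Bxx;
  const double P3 = 1.0 + Byy + t.b * Byy;
  // d(st*P1)/de etc. pick up dst and db; de/dBxx = 1, de/dByy = 2
  const double q1 = t.dst * P1 + t.st * t.db * Bxx;
  const double q3 = t.dst * P3 + t.st * t.db * Byy;
  const double qxy = (t.dst * (1.0 + t.b) + t.st * t.db) * Bxy;
  J[0][0] = -1.0 / c.tau_D - t.st * (1.0 + t.b) - q1;
  J[0][1] = 2.0 * gd;
  J[0][2] = -2.0 * q1;
  J[1][0] = -qxy;
  J[1][1] = -1.0 / c.tau_D - t.st * (1.0 + t.b);
  J[1][2] = gd - 2.0 * qxy;
  J[2][0] = -q3;
  J[2][1] = 0.0;
  J[2][2] = -1.0 / c.tau_D - t.st * (1.0 + t.b) - 2.0 * q3;
}

inline bool solve3(const double A[3][3], const double* b, double* x) {
  // Gaussian elimination with partial pivoting on a copy
  double M[3][4];
  for (int i = 0; i < 3; ++i) {
    for (int j = 0; j < 3; ++j) M[i][j] = A[i][j];
    M[i][3] = b[i];
  }
  for (int k = 0; k < 3; ++k) {
    int p = k;
    for (int i = k + 1; i < 3; ++i)
      if (std::fabs(M[i][k]) > std::fabs(M[p][k])) p = i;
    if (std::fabs(M[p][k]) < 1e-300) return false;
    if (p != k) for (int j = k; j < 4; ++j) std::swap(M[p][j], M[k][j]);
    for (int i = k + 1; i < 3; ++i) {
      const double f = M[i][k] / M[k][k];
      for (int j = k; j < 4; ++j) M[i][j] -= f * M[k][j];
    }
  }
  for (int i = 2; i >= 0; --i) {
    double s = M[i][3];
    for (int j = i + 1; j < 3; ++j) s -= M[i][j] * x[j];
    x[i] = s / M[i][i];
  }
  return true;
}

inline double rnorm_inf(const double* R) {
  double m = std::fabs(R[0]);
  if (std::fabs(R[1]) > m) m = std::fabs(R[1]);
  if (std::fabs(R[2]) > m) m = std::fabs(R[2]);
  return m;
}

inline double res_scale(const double* u, double gd, const RPConst& c) {
  double bmax = std::max(std::fabs(u[0]), std::max(std::fabs(u[1]), std::fabs(u[2])));
  double rate = std::max(gd, std::max(1.0 / c.tau_D, 1.0 / c.tau_R));
  return rate * std::max(1.0, bmax);
}

inline bool in_domain(const double* u, const RPConst& c) {
  Terms t;
  if (!eval_terms(u, c, t)) return false;
  const double Axx = 1.0 + u[0], Ayy = 1.0 + u[2];
  if (Axx <= 0.0 || Ayy <= 0.0) return false;
  return true;
}

// Damped Newton at fixed rate; returns true when the scaled max-norm
// residual drops below rtol.  u is updated in place.
bool newton_point(double* u, double gd, const RPConst& c,
                  double rtol, int max_iter, int* iters_out) {
  Terms t;
  double R[3], Rn[3], J[3][3], d[3], utry[3];
  if (!eval_terms(u, c, t)) return false;
  residual(u, gd, c, t, R);
  double rn = rnorm_inf(R);
  for (int it = 0; it < max_iter; ++it) {
    if (iters_out) *iters_out = it;
    if (rn <= rtol * res_scale(u, gd, c)) return true;
    jacobian(u, gd, c, t, J);
    double mrhs[3] = { -R[0], -R[1], -R[2] };
    if (!solve3(J, mrhs, d)) return false;
    double alpha = 1.0;
    bool ok = false;
    for (int ls = 0; ls < 40; ++ls) {
      utry[0] = u[0] + alpha * d[0];
      utry[1] = u[1] + alpha * d[1];
      utry[2] = u[2] + alpha * d[2];
      Terms tt;
      if (eval_terms(utry, c, tt) && (1.0 + utry[0]) > 0.0 && (1.0 + utry[2]) > 0.0) {
        residual(utry, gd, c, tt, Rn);
        const double rnn = rnorm_inf(Rn);
        if (rnn < rn * (1.0 - 1e-4 * alpha) || rnn <= rtol * res_scale(utry, gd, c)) {
          u[0] = utry[0]; u[1] = utry[1]; u[2] = utry[2];
          t = tt; R[0] = Rn[0]; R[1] = Rn[1]; R[2] = Rn[2];
          rn = rnn; ok = true;
          break;
        }
      }
      alpha *= 0.5;
    }
    if (!ok) return rn <= rtol * res_scale(u, gd, c);
  }
  return rn <= rtol * res_scale(u, gd, c);
}

// Implicit-Euler pseudo-time integration fallback from state u at rate gd.
bool pseudo_time(double* u, double gd, const RPConst& c, double rtol) {
  const double tau_min = std::min(c.tau_R, std::min(c.tau_D, gd > 0 ? 1.0 / gd : c.tau_D));
  double dt = 0.01 * tau_min;
  double R[3];
  Terms t;
  for (int step = 0; step < 200000; ++step) {
    if (!eval_terms(u, c, t)) return false;
    residual(u, gd, c, t, R);
    if (rnorm_inf(R) <= rtol * res_scale(u, gd, c)) return true;
    // one implicit-Euler step: solve (I - dt J) d = dt R, u += d (Newton
    // linearisation of B_{n+1} = B_n + dt * R(B_{n+1}), single correction
    // with step-size control keeps it robust and cheap)
    double J[3][3];
    jacobian(u, gd, c, t, J);
    double M[3][3];
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j)
        M[i][j] = (i == j ? 1.0 : 0.0) - dt * J[i][j];
    double rhs[3] = { dt * R[0], dt * R[1], dt * R[2] };
    double d[3];
    if (!solve3(M, rhs, d)) { dt *= 0.5; continue; }
    double utry[3] = { u[0] + d[0], u[1] + d[1], u[2] + d[2] };
    if (!in_domain(utry, c)) { dt *= 0.5; continue; }
    u[0] = utry[0]; u[1] = utry[1]; u[2] = utry[2];
    dt = std::min(dt * 1.4, 100.0 * tau_min);
  }
  if (!eval_terms(u, c, t)) return false;
  residual(u, gd, c, t, R);
  return rnorm_inf(R) <= rtol * res_scale(u, gd, c);
}

// Continuation march from (g_cur, u) to g_target (both > 0, g_target >= g_cur
// or a fresh start with g_cur == 0).
bool march_to(double& g_cur, double* u, double g_target, const RPConst& c,
              double rtol) {
  const double lstep = 0.2;  // max decades per continuation step
  if (g_cur <= 0.0) {
    // start in the near-linear regime where the equilibrium guess converges
    double tau_max = std::max(c.tau_D, c.tau_R);
    double g0 = std::min(g_target, 0.1 / tau_max);
    int it;
    if (!newton_point(u, g0, c, rtol, 100, &it)) {
      if (!pseudo_time(u, g0, c, rtol)) return false;
    }
    g_cur = g0;
  }
  while (g_cur < g_target * (1.0 - 1e-12)) {
    double g_next = std::min(g_target, g_cur * std::pow(10.0, lstep));
    double usave[3] = { u[0], u[1], u[2] };
    int depth = 0;
    for (;;) {
      int it;
      if (newton_point(u, g_next, c, rtol, 100, &it)) {
        g_cur = g_next;
        break;
      }
      // failed: restore and bisect the step in log space
      u[0] = usave[0]; u[1] = usave[1]; u[2] = usave[2];
      if (++depth > 50 || g_next / g_cur < 1.0 + 1e-12) {
        if (pseudo_time(u, g_next, c, rtol)) { g_cur = g_next; break; }
        return false;
      }
      g_next = std::sqrt(g_cur * g_next);
    }
  }
  return true;
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".rp_steady_sweep_cpp")]]
List rp_steady_sweep_cpp(NumericVector rates, double eta_p, double tau_D,
                         double tau_R, double chi_max, double beta,
                         double eta_s, double delta,
                         double rtol = 1e-10) {
  const int n = rates.size();
  RPConst c { tau_D, tau_R, chi_max * chi_max, beta, delta };
  NumericVector sigma_xy(n), N1(n), Bxx(n), Bxy(n), Byy(n), trA(n), ksv(n);
  LogicalVector conv(n);
  double u[3] = {0.0, 0.0, 0.0};
  double g_cur = 0.0;
  bool dead = false;  // a failed march poisons all later (higher) rates
  for (int i = 0; i < n; ++i) {
    const double gd = rates[i];
    if (gd < 0.0) stop("shear rates must be non-negative");
    if (gd == 0.0) {
      sigma_xy[i] = 0.0; N1[i] = 0.0;
      Bxx[i] = Bxy[i] = Byy[i] = 0.0; trA[i] = 3.0; ksv[i] = 1.0;
      conv[i] = true;
      continue;
    }
    bool ok = !dead && march_to(g_cur, u, gd, c, rtol);
    if (!ok) { dead = true; conv[i] = false; sigma_xy[i] = NA_REAL; N1[i] = NA_REAL;
               Bxx[i] = NA_REAL; Bxy[i] = NA_REAL; Byy[i] = NA_REAL;
               trA[i] = NA_REAL; ksv[i] = NA_REAL; continue; }
    Terms t;
    eval_terms(u, c, t);
    const double G = eta_p / tau_D;  // plateau modulus
    sigma_xy[i] = eta_s * gd + G * t.ks * u[1];
    N1[i] = G * t.ks * (u[0] - u[2]);
    Bxx[i] = u[0]; Bxy[i] = u[1]; Byy[i] = u[2];
    trA[i] = 3.0 + u[0] + 2.0 * u[2];
    ksv[i] = t.ks;
    conv[i] = true;
  }
  return List::create(_["sigma_xy"] = sigma_xy, _["N1"] = N1,
                      _["Bxx"] = Bxx, _["Bxy"] = Bxy, _["Byy"] = Byy,
                      _["trA"] = trA, _["ks"] = ksv, _["converged"] = conv);
}
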