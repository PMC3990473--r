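#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Virtual-cell intracellular dynamics.
//
// State y = (A, X, P_1..P_n): internal resource, internal energy, protein
// concentrations. Gene table rows (one per gene, matching genome order):
//   col 0: category (1 tf, 2 enzyme, 3 pump)
//   col 1: basal expression rate
//   col 2: tf ligand (0 = A, 1 = X) | enzyme reaction (0 catabolic, 1 anabolic)
//   col 3: tf K_lig   | enzyme k_cat | pump k_cat
//   col 4: tf eff_bound | enzyme K_A | pump K_Aext
//   col 5: tf eff_free  | enzyme K_X | pump K_X
//   col 6: pump energy cost per imported A
// env = (A_ext, permeability, degradation, conversion_rate, K_op).
//
// Kinetics (saturating Michaelis-Menten forms):
//   catabolic  v = k_cat * P * A/(K_A+A)                    A -> X (yield: conversion_rate)
//   anabolic   v = k_cat * P * A/(K_A+A) * X/(K_X+X)        A + X -> product (sink)
//   pump       v = k_cat * P * A_ext/(K_Aext+A_ext) * X/(K_X+X)   import, consumes cost*v of X
// Regulation (quasi-steady-state TF binding):
//   bound fraction b = [ligand]/([ligand]+K_lig); promoter occupancy
//   occ = P_tf/(P_tf+K_op); log-rate contribution w = occ*(b*eff_bound+(1-b)*eff_free);
//   expression = basal * exp(sum of w over matching TFs).

struct CellModel {
  int n;
  const double *cat, *basal, *p2, *p3, *p4, *p5, *p6;
  double A_ext, perm, deg, conv, K_op;
  std::vector<std::vector<int>> reg; // 0-based regulator indices per gene
  std::vector<double> w;             // per-gene regulator contribution buffer

  CellModel(const NumericMatrix& genes, const List& regulators,
            const NumericVector& env)
      : n(genes.nrow()), w(genes.nrow(), 0.0) {
    cols.assign(7 * (size_t)n, 0.0);
    for (int j = 0; j < 7; ++j)
      for (int i = 0; i < n; ++i) cols[(size_t)j * n + i] = genes(i, j);
    cat = cols.data(); basal = cols.data() + (size_t)1 * n;
    p2 = cols.data() + (size_t)2 * n; p3 = cols.data() + (size_t)3 * n;
    p4 = cols.data() + (size_t)4 * n; p5 = cols.data() + (size_t)5 * n;
    p6 = cols.data() + (size_t)6 * n;
    A_ext = env[0]; perm = env[1]; deg = env[2]; conv = env[3]; K_op = env[4];
    reg.resize(n);
    for (int i = 0; i < n; ++i) {
      IntegerVector r = regulators[i];
      reg[i].assign(r.begin(), r.end());
      for (size_t k = 0; k < reg[i].size(); ++k) reg[i][k] -= 1; // to 0-based
    }
  }

  std::vector<double> cols;

  void deriv(const double* y, double* f) {
    const double A = y[0], X = y[1];
    const double* P = y + 2;
    // TF regulatory weights under quasi-steady-state ligand binding
    for (int i = 0; i < n; ++i) {
      if (cat[i] == 1.0) {
        const double lig = (p2[i] == 0.0) ? A : X;
        const double b = lig / (lig + p3[i]);
        const double occ = P[i] / (P[i] + K_op);
        w[i] = occ * (b * p4[i] + (1.0 - b) * p5[i]);
      }
    }
    double dA = perm * (A_ext - A), dX = 0.0;
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (size_t k = 0; k < reg[i].size(); ++k) s += w[reg[i][k]];
      const double expr = basal[i] * std::exp(s);
      f[2 + i] = expr - deg * P[i];
      if (cat[i] == 2.0) { // enzyme
        const double satA = A / (p4[i] + A);
        if (p2[i] == 0.0) { // catabolic A -> X
          const double v = p3[i] * P[i] * satA;
          dA -= v; dX += conv * v;
        } else {            // anabolic A + X -> product
          const double v = p3[i] * P[i] * satA * (X / (p5[i] + X));
          dA -= v; dX -= v;
        }
      } else if (cat[i] == 3.0) { // pump
        const double v = p3[i] * P[i] * (A_ext / (p4[i] + A_ext)) * (X / (p5[i] + X));
        dA += v; dX -= p6[i] * v;
      }
    }
    f[0] = dA; f[1] = dX;
  }
};

// Cash-Karp embedded Runge-Kutta 4(5) coefficients
static const double b21 = 1.0 / 5.0;
static const double b31 = 3.0 / 40.0, b32 = 9.0 / 40.0;
static const double b41 = 3.0 / 10.0, b42 = -9.0 / 10.0, b43 = 6.0 / 5.0;
static const double b51 = -11.0 / 54.0, b52 = 5.0 / 2.0, b53 = -70.0 / 27.0,
                    b54 = 35.0 / 27.0;
static const double b61 = 1631.0 / 55296.0, b62 = 175.0 / 512.0,
                    b63 = 575.0 / 13824.0, b64 = 44275.0 / 110592.0,
                    b65 = 253.0 / 4096.0;
static const double c1 = 37.0 / 378.0, c3 = 250.0 / 621.0, c4 = 125.0 / 594.0,
                    c6 = 512.0 / 1771.0;
static const double d1 = c1 - 2825.0 / 27648.0, d3 = c3 - 18575.0 / 48384.0,
                    d4 = c4 - 13525.0 / 55296.0, d5 = -277.0 / 14336.0,
                    d6 = c6 - 1.0 / 4.0;

static double max_rel_deriv(const std::vector<double>& y,
                            const std::vector<double>& f) {
  double mrel = 0.0;
  for (size_t i = 0; i < y.size(); ++i)
    mrel = std::max(mrel, std::fabs(f[i]) / (1.0 + std::fabs(y[i])));
  return mrel;
}

// Nonlinear power iteration for the Jacobian spectral radius, as used by
// stabilized explicit (Runge-Kutta-Chebyshev) solvers.
static double spectral_radius(CellModel& m, const std::vector<double>& y,
                              const std::vector<double>& fy,
                              std::vector<double>& eigvec) {
  const int d = (int)y.size();
  double ynorm = 0.0;
  for (int i = 0; i < d; ++i) ynorm += y[i] * y[i];
  ynorm = std::sqrt(ynorm);
  const double small = 1e-7 * (1.0 + ynorm);
  double vnorm = 0.0;
  for (int i = 0; i < d; ++i) vnorm += eigvec[i] * eigvec[i];
  vnorm = std::sqrt(vnorm);
  std::vector<double> v(d), fv(d);
  if (vnorm == 0.0) { eigvec.assign(d, 1.0); vnorm = std::sqrt((double)d); }
  for (int i = 0; i < d; ++i) v[i] = y[i] + small * eigvec[i] / vnorm;
  double lambda = 0.0, lambda_old = 0.0;
  for (int it = 0; it < 12; ++it) {
    m.deriv(v.data(), fv.data());
    double dnorm = 0.0;
    for (int i = 0; i < d; ++i) {
      fv[i] -= fy[i];
      dnorm += fv[i] * fv[i];
    }
    dnorm = std::sqrt(dnorm);
    lambda = dnorm / small;
    if (dnorm == 0.0) break;
    for (int i = 0; i < d; ++i) v[i] = y[i] + small * fv[i] / dnorm;
    if (it > 1 && std::fabs(lambda - lambda_old) < 0.05 * lambda) break;
    lambda_old = lambda;
  }
  for (int i = 0; i < d; ++i) eigvec[i] = v[i] - y[i];
  return 1.2 * lambda + 1e-12;
}

// One RKC2 step of `s` stages (damped Chebyshev recursion, damping 2/13).
static void rkc_step(CellModel& m, const std::vector<double>& y,
                     const std::vector<double>& f0, double h, int s,
                     std::vector<double>& ynew, std::vector<double>& fnew,
                     std::vector<double>& err) {
  if (s < 2) s = 2;
  if (s > 200) s = 200;
  const int d = (int)y.size();
  const double eps_d = 2.0 / 13.0;
  const double w0 = 1.0 + eps_d / (double)(s * s);
  // Chebyshev values at w0 by recursion
  std::vector<double> T(s + 1), Tp(s + 1), Tpp(s + 1);
  T[0] = 1.0; Tp[0] = 0.0; Tpp[0] = 0.0;
  T[1] = w0; Tp[1] = 1.0; Tpp[1] = 0.0;
  for (int j = 2; j <= s; ++j) {
    T[j] = 2.0 * w0 * T[j - 1] - T[j - 2];
    Tp[j] = 2.0 * T[j - 1] + 2.0 * w0 * Tp[j - 1] - Tp[j - 2];
    Tpp[j] = 4.0 * Tp[j - 1] + 2.0 * w0 * Tpp[j - 1] - Tpp[j - 2];
  }
  const double w1 = Tp[s] / Tpp[s];
  std::vector<double> b(s + 1);
  for (int j = 2; j <= s; ++j) b[j] = Tpp[j] / (Tp[j] * Tp[j]);
  b[0] = b[1] = b[2];
  std::vector<double> yjm2(y), yjm1(d), fj(d);
  const double mu1t = b[1] * w1;
  for (int i = 0; i < d; ++i) yjm1[i] = y[i] + h * mu1t * f0[i];
  for (int j = 2; j <= s; ++j) {
    m.deriv(yjm1.data(), fj.data());
    const double mu = 2.0 * b[j] * w0 / b[j - 1];
    const double nu = -b[j] / b[j - 2];
    const double mut = 2.0 * b[j] * w1 / b[j - 1];
    const double ajm1 = 1.0 - b[j - 1] * T[j - 1];
    const double gt = -ajm1 * mut;
    for (int i = 0; i < d; ++i) {
      const double yj = (1.0 - mu - nu) * y[i] + mu * yjm1[i] + nu * yjm2[i] +
                        h * mut * fj[i] + h * gt * f0[i];
      yjm2[i] = yjm1[i];
      yjm1[i] = yj;
    }
  }
  ynew = yjm1;
  m.deriv(ynew.data(), fnew.data());
  for (int i = 0; i < d; ++i)
    err[i] = 0.8 * (y[i] - ynew[i]) + 0.4 * h * (f0[i] + fnew[i]);
}

// Newton refinement of a nearby fixed point, used once the integrated
// trajectory has almost settled (finite-difference Jacobian, Gaussian
// elimination with partial pivoting, damped non-negative updates). The
// refined point must stay close to the gate state so we only ever converge
// to the attractor the trajectory was approaching; limit cycles and
// drifting states fail the gate or the locality check and keep integrating.
static bool newton_refine(CellModel& m, std::vector<double>& y,
                          double conv_tol) {
  const int d = (int)y.size();
  std::vector<double> f(d), y0(y), J((size_t)d * d), fp(d), yp(d), rhs(d);
  std::vector<int> piv(d);
  m.deriv(y.data(), f.data());
  double prev_res = max_rel_deriv(y, f);
  for (int it = 0; it < 6; ++it) {
    for (int j = 0; j < d; ++j) {
      const double eps = 1e-7 * (1.0 + std::fabs(y[j]));
      yp = y;
      yp[j] += eps;
      m.deriv(yp.data(), fp.data());
      for (int i = 0; i < d; ++i) J[(size_t)i * d + j] = (fp[i] - f[i]) / eps;
    }
    for (int i = 0; i < d; ++i) rhs[i] = -f[i];
    // LU with partial pivoting, in place
    for (int k = 0; k < d; ++k) {
      int p = k;
      double big = std::fabs(J[(size_t)k * d + k]);
      for (int i = k + 1; i < d; ++i) {
        const double v = std::fabs(J[(size_t)i * d + k]);
        if (v > big) { big = v; p = i; }
      }
      if (big < 1e-14) return false; // singular
      if (p != k) {
        for (int j = 0; j < d; ++j)
          std::swap(J[(size_t)k * d + j], J[(size_t)p * d + j]);
        std::swap(rhs[k], rhs[p]);
      }
      const double pivv = J[(size_t)k * d + k];
      for (int i = k + 1; i < d; ++i) {
        const double fac = J[(size_t)i * d + k] / pivv;
        if (fac == 0.0) continue;
        for (int j = k + 1; j < d; ++j)
          J[(size_t)i * d + j] -= fac * J[(size_t)k * d + j];
        rhs[i] -= fac * rhs[k];
      }
    }
    for (int i = d - 1; i >= 0; --i) {
      double s = rhs[i];
      for (int j = i + 1; j < d; ++j) s -= J[(size_t)i * d + j] * rhs[j];
      rhs[i] = s / J[(size_t)i * d + i];
    }
    double maxrel_step = 0.0;
    for (int i = 0; i < d; ++i)
      maxrel_step = std::max(maxrel_step,
                             std::fabs(rhs[i]) / (1.0 + std::fabs(y[i])));
    if (!std::isfinite(maxrel_step)) return false;
    double lam = maxrel_step > 0.5 ? 0.5 / maxrel_step : 1.0;
    for (int i = 0; i < d; ++i) {
      y[i] += lam * rhs[i];
      if (y[i] < 0.0) y[i] = 0.0;
    }
    m.deriv(y.data(), f.data());
    const double mrel = max_rel_deriv(y, f);
    if (!std::isfinite(mrel)) return false;
    if (it >= 1 && mrel > 0.7 * prev_res) return false; // not contracting
    prev_res = std::min(prev_res, mrel);
    if (mrel < conv_tol) {
      for (int i = 0; i < d; ++i)
        if (std::fabs(y[i] - y0[i]) > 0.5 * (1.0 + std::fabs(y0[i])))
          return false; // refined to a different basin: reject
      return true;
    }
  }
  return false;
}

static List integrate_rkc(CellModel& m, std::vector<double> y, double t_max,
                          double rtol, double atol, double conv_tol,
                          double h_max, double f_max) {
  const int d = (int)y.size();
  std::vector<double> f(d), ynew(d), fnew(d), err(d), eigvec(d, 0.0);
  double t = 0.0;
  bool converged = false, diverged = false;
  long steps = 0;
  const long max_steps = 100000;
  // budget on right-hand-side evaluations (one per Chebyshev stage):
  // healthy cells converge within a few hundred; cells that exhaust the
  // budget have no resolvable steady state on the homeostasis timescale
  long fbudget = (long)f_max;
  m.deriv(y.data(), f.data());
  if (max_rel_deriv(y, f) < conv_tol) converged = true;
  double sprad = 0.0;
  long last_sprad = -100;
  long last_newton = -100;
  int newton_tries = 0;
  double h = 0.0;
  while (!converged && !diverged && t < t_max && steps < max_steps &&
         fbudget > 0) {
    if (steps - last_sprad >= 25 || sprad == 0.0) {
      sprad = spectral_radius(m, y, f, eigvec);
      last_sprad = steps;
    }
    if (!std::isfinite(sprad) || sprad > 1e8) {
      // timescales this fast only arise from runaway regulation; the cell
      // has no biologically meaningful steady state
      diverged = true;
      break;
    }
    if (h == 0.0) h = std::min(h_max, std::max(1e-4, 0.1 / sprad));
    if (h > h_max) h = h_max;
    if (t + h > t_max) h = t_max - t;
    double s_d = 1.0 + std::ceil(std::sqrt(std::max(0.0, h * sprad / 0.653)));
    if (!(s_d >= 2.0)) s_d = 2.0;
    int s;
    if (s_d > 200.0) {
      h = 0.653 * 200.0 * 200.0 / sprad;
      s = 200;
      if (t + h > t_max) h = t_max - t;
    } else {
      s = (int)s_d;
    }
    rkc_step(m, y, f, h, s, ynew, fnew, err);
    fbudget -= s;
    double errn = 0.0;
    bool finite = true;
    for (int i = 0; i < d; ++i) {
      if (!std::isfinite(ynew[i])) { finite = false; break; }
      const double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
      errn = std::max(errn, std::fabs(err[i]) / sc);
    }
    ++steps;
    if (!finite || !std::isfinite(errn)) {
      h *= 0.25;
      sprad = 0.0; // force re-estimate
      if (h < 1e-10) { diverged = true; break; }
      continue;
    }
    if (errn <= 1.0) {
      t += h;
      bool clamped = false;
      for (int i = 0; i < d; ++i) {
        y[i] = ynew[i] < 0.0 ? 0.0 : ynew[i];
        if (y[i] > 1e12) diverged = true;
        if (y[i] != ynew[i]) clamped = true;
      }
      if (diverged) break;
      if (clamped) m.deriv(y.data(), f.data()); else f = fnew;
      const double mrel = max_rel_deriv(y, f);
      if (mrel < conv_tol) { converged = true; break; }
      // nearly settled: refine the nearby fixed point directly
      if (mrel < 0.05 && newton_tries < 3 && steps - last_newton > 20) {
        ++newton_tries;
        last_newton = steps;
        std::vector<double> yn(y);
        if (newton_refine(m, yn, conv_tol)) {
          y = yn;
          converged = true;
          break;
        }
        m.deriv(y.data(), f.data());
      }
      double fac = 0.8 * std::pow(1.0 / errn, 1.0 / 3.0);
      if (fac > 10.0) fac = 10.0;
      if (fac < 0.1) fac = 0.1;
      h *= fac;
    } else {
      double fac = 0.8 * std::pow(1.0 / errn, 1.0 / 3.0);
      if (fac < 0.1) fac = 0.1;
      h *= fac;
      if (h < 1e-10) { diverged = true; break; }
    }
  }
  return List::create(_["state"] = NumericVector(y.begin(), y.end()),
                      _["converged"] = converged, _["diverged"] = diverged,
                      _["t"] = t, _["steps"] = (double)steps);
}

// [[Rcpp::export(name = "cc_steady_state")]]
List cc_steady_state(NumericMatrix genes, List regulators, NumericVector env,
                     NumericVector init, double t_max = 1000.0,
                     double rtol = 1e-6, double atol = 1e-8,
                     double conv_tol = 1e-6, double h_max = 25.0,
                     std::string method = "rkc", double f_max = 50000) {
  CellModel m(genes, regulators, env);
  const int d = m.n + 2;
  std::vector<double> y(init.begin(), init.end());
  if ((int)y.size() != d) stop("init state has wrong length");
  if (method == "rkc")
    return integrate_rkc(m, y, t_max, rtol, atol, conv_tol, h_max, f_max);
  if (method != "rk45") stop("unknown integration method");
  std::vector<double> f(d), k2(d), k3(d), k4(d), k5(d), k6(d), ytmp(d), yerr(d),
      ynew(d);
  double t = 0.0, h = 0.01;
  bool converged = false, diverged = false;
  long steps = 0;
  const long max_steps = 2000000;

  m.deriv(y.data(), f.data());
  // already at (or started on) an equilibrium
  {
    double mrel = 0.0;
    for (int i = 0; i < d; ++i)
      mrel = std::max(mrel, std::fabs(f[i]) / (1.0 + std::fabs(y[i])));
    if (mrel < conv_tol) converged = true;
  }

  while (!converged && !diverged && t < t_max && steps < max_steps) {
    if (h > h_max) h = h_max;
    if (t + h > t_max) h = t_max - t;
    for (int i = 0; i < d; ++i) ytmp[i] = y[i] + h * b21 * f[i];
    m.deriv(ytmp.data(), k2.data());
    for (int i = 0; i < d; ++i) ytmp[i] = y[i] + h * (b31 * f[i] + b32 * k2[i]);
    m.deriv(ytmp.data(), k3.data());
    for (int i = 0; i < d; ++i)
      ytmp[i] = y[i] + h * (b41 * f[i] + b42 * k2[i] + b43 * k3[i]);
    m.deriv(ytmp.data(), k4.data());
    for (int i = 0; i < d; ++i)
      ytmp[i] = y[i] + h * (b51 * f[i] + b52 * k2[i] + b53 * k3[i] + b54 * k4[i]);
    m.deriv(ytmp.data(), k5.data());
    for (int i = 0; i < d; ++i)
      ytmp[i] = y[i] + h * (b61 * f[i] + b62 * k2[i] + b63 * k3[i] +
                            b64 * k4[i] + b65 * k5[i]);
    m.deriv(ytmp.data(), k6.data());
    double err = 0.0;
    for (int i = 0; i < d; ++i) {
      ynew[i] = y[i] + h * (c1 * f[i] + c3 * k3[i] + c4 * k4[i] + c6 * k6[i]);
      yerr[i] = h * (d1 * f[i] + d3 * k3[i] + d4 * k4[i] + d5 * k5[i] + d6 * k6[i]);
      const double sc = atol + rtol * std::fabs(y[i]);
      err = std::max(err, std::fabs(yerr[i]) / sc);
    }
    ++steps;
    if (!std::isfinite(err)) { diverged = true; break; }
    if (err <= 1.0) {
      t += h;
      for (int i = 0; i < d; ++i) y[i] = ynew[i] < 0.0 ? 0.0 : ynew[i];
      for (int i = 0; i < d; ++i)
        if (!std::isfinite(y[i]) || y[i] > 1e12) { diverged = true; break; }
      if (diverged) break;
      m.deriv(y.data(), f.data());
      double mrel = 0.0;
      for (int i = 0; i < d; ++i)
        mrel = std::max(mrel, std::fabs(f[i]) / (1.0 + std::fabs(y[i])));
      if (mrel < conv_tol) { converged = true; break; }
      double fac = 0.9 * std::pow(err, -0.2);
      if (fac > 5.0) fac = 5.0;
      h *= fac;
    } else {
      double fac = 0.9 * std::pow(err, -0.25);
      if (fac < 0.1) fac = 0.1;
      h *= fac;
      if (h < 1e-10) { diverged = true; break; }
    }
  }
  return List::create(_["state"] = NumericVector(y.begin(), y.end()),
                      _["converged"] = converged, _["diverged"] = diverged,
                      _["t"] = t, _["steps"] = (double)steps);
}

// [[Rcpp::export(name = "cc_derivatives")]]
NumericVector cc_derivatives(NumericMatrix genes, List regulators,
                             NumericVector env, NumericVector state) {
  CellModel m(genes, regulators, env);
  std::vector<double> y(state.begin(), state.end()), f(m.n + 2);
  m.deriv(y.data(), f.data());
  return NumericVector(f.begin(), f.end());
}

// Fast path for population evaluation: score one cell in several resource
// conditions (A_ext values) without returning trajectories. The initial
// state per evaluation is A_int = A_ext, X_int = target_X, proteins at
// basal/degradation.
// [[Rcpp::export(name = "cc_eval_scores")]]
NumericVector cc_eval_scores(NumericMatrix genes, List regulators,
                             NumericVector env, NumericVector A_ext_values,
                             double target_A, double target_X,
                             double t_max = 300.0, double rtol = 1e-6,
                             double atol = 1e-8, double conv_tol = 1e-6,
                             double h_max = 25.0, std::string method = "rkc",
                             double f_max = 50000) {
  const int n = genes.nrow();
  NumericVector out(A_ext_values.size());
  CellModel m(genes, regulators, env);
  std::vector<double> init(n + 2);
  for (int k = 0; k < A_ext_values.size(); ++k) {
    m.A_ext = A_ext_values[k];
    init[0] = A_ext_values[k];
    init[1] = target_X;
    for (int i = 0; i < n; ++i) init[2 + i] = m.basal[i] / m.deg;
    List res;
    if (method == "rkc") {
      res = integrate_rkc(m, init, t_max, rtol, atol, conv_tol, h_max, f_max);
    } else {
      NumericVector env_k = clone(env);
      env_k[0] = A_ext_values[k];
      res = cc_steady_state(genes, regulators, env_k,
                            NumericVector(init.begin(), init.end()), t_max,
                            rtol, atol, conv_tol, h_max, method, f_max);
    }
    bool ok = as<bool>(res["converged"]) && !as<bool>(res["diverged"]);
    if (!ok) { out[k] = 0.0; continue; }
    NumericVector y = res["state"];
    const double devA = std::fabs(y[0] - target_A) / target_A;
    const double devX = std::fabs(y[1] - target_X) / target_X;
    out[k] = 1.0 / (1.0 + devA + devX);
  }
  return out;
}
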