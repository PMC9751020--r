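// Numerical core for the intramembrane-cavitation point neuron:
//  - molecular (inter-leaflet) pressure quadrature and its Z-lookup
//  - deflection-dependent membrane capacitance
//  - adaptive Cash-Karp integration of the sonophore Rayleigh-Plesset system
//  - brute-force co-integration oracle (mechanics + Hodgkin-Huxley membrane)
//  - effective-variable (cycle-averaged) integration of the charge-cast membrane
//
// Units: SI for mechanics (m, s, Pa, mol). Electrical: charge density in C/m^2,
// capacitance in F/m^2, conductances in S/m^2; voltages handed to the rate
// functions in mV (the HH rate constants are conventionally written in mV/ms).

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Parameter bundles
// ---------------------------------------------------------------------------

struct BLS {
  double a, T, Rg, Ar, xrep, yatt, dstar, P0, ks, eps0, epsr;
  double rhol, mul, mus, delta0, Dgl, xi, Cm0, kH, Delta, Cg, S0;
  // uniform-grid lookup of the molecular pressure PM(Z)
  double pm_z0, pm_dz;
  std::vector<double> pm;

  double pm_at(double Z) const {
    // trial stages of the adaptive integrator may probe wild states;
    // any non-finite or out-of-range deflection clamps to the table edge
    double u = (Z - pm_z0) / pm_dz;
    if (!std::isfinite(u) || u <= 0.0) return pm.front();
    double umax = (double)(pm.size() - 1);
    if (u >= umax) return pm.back();
    int i = (int)u;
    double f = u - i;
    return pm[i] * (1.0 - f) + pm[i + 1] * f;
  }
};

struct RS {
  double gNa, gKd, gM, gLeak;   // S/m^2
  double VNa, VK, VLeak, VT;    // mV
  double tau_max;               // s
  double Cm0;                   // F/m^2
};

static BLS make_bls(const List& P) {
  BLS b;
  b.a = P["a"]; b.T = P["T"]; b.Rg = P["Rg"]; b.Ar = P["Ar"];
  b.xrep = P["x_rep"]; b.yatt = P["y_att"]; b.dstar = P["delta_star"];
  b.P0 = P["P0"]; b.ks = P["ks"]; b.eps0 = P["eps0"]; b.epsr = P["eps_r"];
  b.rhol = P["rho_l"]; b.mul = P["mu_l"]; b.mus = P["mu_s"];
  b.delta0 = P["delta0"]; b.Dgl = P["Dgl"]; b.xi = P["xi"];
  b.Cm0 = P["Cm0"]; b.kH = P["kH"]; b.Delta = P["Delta"]; b.Cg = P["Cg"];
  b.S0 = M_PI * b.a * b.a;
  if (P.containsElementNamed("pm_z")) {
    NumericVector z = P["pm_z"];
    NumericVector v = P["pm_val"];
    b.pm_z0 = z[0];
    b.pm_dz = z[1] - z[0];
    b.pm.assign(v.begin(), v.end());
  } else {
    b.pm_z0 = 0.0; b.pm_dz = 1.0;
  }
  return b;
}

static RS make_rs(const List& P) {
  RS r;
  r.gNa = P["gNa"]; r.gKd = P["gKd"]; r.gM = P["gM"]; r.gLeak = P["gLeak"];
  r.VNa = P["VNa"]; r.VK = P["VK"]; r.VLeak = P["VLeak"]; r.VT = P["VT"];
  r.tau_max = P["tau_max"]; r.Cm0 = P["Cm0"];
  return r;
}

// ---------------------------------------------------------------------------
// Sonophore geometry and pressures
// ---------------------------------------------------------------------------

// local deflection of one leaflet at radius r, spherical-cap profile
static inline double cap_z(double Z, double r, double a) {
  if (std::fabs(Z) < 1e-14) return Z * (1.0 - r * r / (a * a));
  double R = (a * a + Z * Z) / (2.0 * Z);
  double s = (Z > 0.0) ? 1.0 : -1.0;
  return (Z - R) + s * std::sqrt(R * R - r * r);
}

// direct Gauss-Legendre quadrature of the inter-leaflet molecular pressure
static double pm_direct(double Z, const BLS& b, const std::vector<double>& gx,
                        const std::vector<double>& gw) {
  // PM = (2 pi Ar / S(Z)) * int_0^a [ (d*/zeta)^x - (d*/zeta)^y ] r dr
  double acc = 0.0;
  double a = b.a;
  for (size_t k = 0; k < gx.size(); ++k) {
    double r = 0.5 * a * (gx[k] + 1.0);        // map [-1,1] -> [0,a]
    double w = 0.5 * a * gw[k];
    double zeta = b.Delta + 2.0 * cap_z(Z, r, a);
    double u = b.dstar / zeta;
    acc += w * r * (std::pow(u, b.xrep) - std::pow(u, b.yatt));
  }
  double S = M_PI * (a * a + Z * Z);
  return 2.0 * M_PI * b.Ar * acc / S;
}

// Gauss-Legendre nodes/weights on [-1,1] (Newton iteration on P_n)
static void gauleg(int n, std::vector<double>& x, std::vector<double>& w) {
  x.resize(n); w.resize(n);
  int m = (n + 1) / 2;
  for (int i = 0; i < m; ++i) {
    double z = std::cos(M_PI * (i + 0.75) / (n + 0.5)), z1, pp = 0.0;
    do {
      double p1 = 1.0, p2 = 0.0;
      for (int j = 0; j < n; ++j) {
        double p3 = p2; p2 = p1;
        p1 = ((2.0 * j + 1.0) * z * p2 - j * p3) / (j + 1.0);
      }
      pp = n * (z * p1 - p2) / (z * z - 1.0);
      z1 = z; z = z1 - p1 / pp;
    } while (std::fabs(z - z1) > 1e-15);
    x[i] = -z; x[n - 1 - i] = z;
    w[i] = 2.0 / ((1.0 - z * z) * pp * pp);
    w[n - 1 - i] = w[i];
  }
}

// [[Rcpp::export]]
NumericVector pm_profile_cpp(NumericVector Z, List params, int nodes) {
  BLS b = make_bls(params);
  std::vector<double> gx, gw;
  gauleg(nodes, gx, gw);
  NumericVector out(Z.size());
  for (R_xlen_t i = 0; i < Z.size(); ++i) out[i] = pm_direct(Z[i], b, gx, gw);
  return out;
}

// membrane capacitance as a function of apex deflection
static inline double cm_of_Z(double Z, double a, double Delta, double Cm0) {
  // catastrophic cancellation sets in below |Z| ~ 1e-12 m; switch to the
  // series Cm0 (1 - Z/Delta + (4/3)(Z/Delta)^2) there
  if (std::fabs(Z) < 1e-12) {
    double r = Z / Delta;
    return Cm0 * (1.0 - r + 4.0 / 3.0 * r * r);
  }
  double a2 = a * a;
  double L = std::log((2.0 * Z + Delta) / Delta);
  return Cm0 * (Delta / a2) * (Z + (a2 - Z * Z - Z * Delta) / (2.0 * Z) * L);
}

static inline double dcm_dZ(double Z, double a, double Delta, double Cm0) {
  double a2 = a * a;
  if (std::fabs(Z) < 1e-12)
    return -(Cm0 / Delta) * (1.0 - 8.0 / 3.0 * Z / Delta);
  double L = std::log((2.0 * Z + Delta) / Delta);
  double t = 1.0 - (a2 + Z * Z) * L / (2.0 * Z * Z)
             + (a2 - Z * Z - Z * Delta) / (Z * (2.0 * Z + Delta));
  return Cm0 * (Delta / a2) * t;
}

// [[Rcpp::export]]
NumericVector cm_cpp(NumericVector Z, List params) {
  BLS b = make_bls(params);
  NumericVector out(Z.size());
  for (R_xlen_t i = 0; i < Z.size(); ++i)
    out[i] = cm_of_Z(Z[i], b.a, b.Delta, b.Cm0);
  return out;
}

// [[Rcpp::export]]
NumericVector dcm_cpp(NumericVector Z, List params) {
  BLS b = make_bls(params);
  NumericVector out(Z.size());
  for (R_xlen_t i = 0; i < Z.size(); ++i)
    out[i] = dcm_dZ(Z[i], b.a, b.Delta, b.Cm0);
  return out;
}

// quasi-static equilibrium deflection at charge Qm (gas at Henry equilibrium)
static double equilibrium_Z(double Qm, const BLS& b) {
  // root of g(Z) = PM(Z) + Pec(Z,Qm) - Ps(Z); g(0) = P0 + Pec > 0 for the
  // parameter sets of interest, g decreasing in Z
  double lo = 0.0, hi = 1e-9;
  auto g = [&](double Z) {
    double a2 = b.a * b.a;
    double S = M_PI * (a2 + Z * Z);
    double rc = 2.0 * Z / (a2 + Z * Z);
    double Pec = -(b.S0 / S) * Qm * Qm / (2.0 * b.eps0 * b.epsr);
    double Ps = b.ks * rc * (S - b.S0) / b.S0;
    return b.pm_at(Z) + Pec - Ps;
  };
  if (g(0.0) <= 0.0) return 0.0;
  while (g(hi) > 0.0 && hi < 64e-9) hi *= 2.0;
  for (int it = 0; it < 200; ++it) {
    double mid = 0.5 * (lo + hi);
    if (g(mid) > 0.0) lo = mid; else hi = mid;
  }
  return 0.5 * (lo + hi);
}

// [[Rcpp::export]]
double bls_equilibrium_cpp(double Qm, List params) {
  BLS b = make_bls(params);
  return equilibrium_Z(Qm, b);
}

// ---------------------------------------------------------------------------
// Hodgkin-Huxley rate constants (regular-spiking cortical point neuron)
// ---------------------------------------------------------------------------

static inline double vtrap(double x, double k) {
  // x / (1 - exp(-x/k)), continuous through x = 0
  if (std::fabs(x / k) < 1e-7) return k + 0.5 * x;
  return x / (1.0 - std::exp(-x / k));
}

// Rate cap (1/s). During sonication the instantaneous intra-cycle potential
// V(t) = Qm/Cm(t) can reach several hundred mV of hyperpolarization, where the
// exponential rate laws blow up numerically (>1e20/s) without changing the
// gate dynamics: any rate far above the acoustic-cycle average acts as
// instantaneous equilibration. Capping at 1e5/s leaves all rates below
// ~+150 mV untouched and keeps the averaged system integrable.
static const double RATE_CAP = 1e5;

// rates in 1/s, V in mV
static inline void hh_rates(double V, const RS& r, double* al, double* be) {
  double vt = V - r.VT;
  al[0] = 1e3 * 0.32 * vtrap(vt - 13.0, 4.0);            // alpha_m
  be[0] = 1e3 * 0.28 * vtrap(-(vt - 40.0), 5.0);         // beta_m
  al[1] = 1e3 * 0.128 * std::exp(-(vt - 17.0) / 18.0);   // alpha_h
  be[1] = 1e3 * 4.0 / (1.0 + std::exp(-(vt - 40.0) / 5.0)); // beta_h
  al[2] = 1e3 * 0.032 * vtrap(vt - 15.0, 5.0);           // alpha_n
  be[2] = 1e3 * 0.5 * std::exp(-(vt - 10.0) / 40.0);     // beta_n
  double pinf = 1.0 / (1.0 + std::exp(-(V + 35.0) / 10.0));
  double taup = r.tau_max / (3.3 * std::exp((V + 35.0) / 20.0)
                             + std::exp(-(V + 35.0) / 20.0));
  al[3] = pinf / taup;                                   // alpha_p
  be[3] = (1.0 - pinf) / taup;                           // beta_p
  for (int k = 0; k < 4; ++k) {
    if (al[k] > RATE_CAP) al[k] = RATE_CAP;
    if (be[k] > RATE_CAP) be[k] = RATE_CAP;
  }
}

// [[Rcpp::export]]
NumericMatrix rs_rates_cpp(NumericVector V, List rs) {
  RS r = make_rs(rs);
  NumericMatrix out(V.size(), 8);
  colnames(out) = CharacterVector::create("alpha_m", "beta_m", "alpha_h",
                                          "beta_h", "alpha_n", "beta_n",
                                          "alpha_p", "beta_p");
  double al[4], be[4];
  for (R_xlen_t i = 0; i < V.size(); ++i) {
    hh_rates(V[i], r, al, be);
    for (int k = 0; k < 4; ++k) { out(i, 2 * k) = al[k]; out(i, 2 * k + 1) = be[k]; }
  }
  return out;
}

// membrane current density, V in mV -> A/m^2
static inline double i_mem(double V, double m, double h, double n, double p,
                           const RS& r) {
  double iNa = r.gNa * m * m * m * h * (V - r.VNa);
  double iKd = r.gKd * n * n * n * n * (V - r.VK);
  double iM = r.gM * p * (V - r.VK);
  double iL = r.gLeak * (V - r.VLeak);
  return (iNa + iKd + iM + iL) * 1e-3;   // mV * S/m^2 -> A/m^2
}

// [[Rcpp::export]]
List rs_steady_cpp(List rs) {
  RS r = make_rs(rs);
  // bracket the resting potential by scanning the steady-state current
  double al[4], be[4];
  auto iinf = [&](double V) {
    hh_rates(V, r, al, be);
    double m = al[0] / (al[0] + be[0]);
    double h = al[1] / (al[1] + be[1]);
    double n = al[2] / (al[2] + be[2]);
    double p = al[3] / (al[3] + be[3]);
    return i_mem(V, m, h, n, p, r);
  };
  double lo = NA_REAL, hi = NA_REAL;
  double prevV = -95.0, prevI = iinf(prevV);
  for (double V = -94.0; V <= -40.0; V += 0.5) {
    double I = iinf(V);
    if (prevI < 0.0 && I >= 0.0) { lo = prevV; hi = V; break; }
    prevV = V; prevI = I;
  }
  if (!R_finite(lo)) stop("could not bracket the resting potential");
  for (int it = 0; it < 100; ++it) {
    double mid = 0.5 * (lo + hi);
    if (iinf(mid) < 0.0) lo = mid; else hi = mid;
  }
  double V0 = 0.5 * (lo + hi);
  hh_rates(V0, r, al, be);
  return List::create(
    _["Vm0"] = V0,
    _["Qm0"] = r.Cm0 * V0 * 1e-3,
    _["m0"] = al[0] / (al[0] + be[0]),
    _["h0"] = al[1] / (al[1] + be[1]),
    _["n0"] = al[2] / (al[2] + be[2]),
    _["p0"] = al[3] / (al[3] + be[3]));
}

// ---------------------------------------------------------------------------
// Adaptive Cash-Karp RK45 integrator (fixed small state dimension)
// ---------------------------------------------------------------------------

static const double CK_A[6] = {0.0, 0.2, 0.3, 0.6, 1.0, 0.875};
static const double CK_B[6][5] = {
  {0, 0, 0, 0, 0},
  {0.2, 0, 0, 0, 0},
  {3.0 / 40.0, 9.0 / 40.0, 0, 0, 0},
  {0.3, -0.9, 1.2, 0, 0},
  {-11.0 / 54.0, 2.5, -70.0 / 27.0, 35.0 / 27.0, 0},
  {1631.0 / 55296.0, 175.0 / 512.0, 575.0 / 13824.0,
   44275.0 / 110592.0, 253.0 / 4096.0}};
static const double CK_C[6] = {37.0 / 378.0, 0.0, 250.0 / 621.0,
                               125.0 / 594.0, 0.0, 512.0 / 1771.0};
static const double CK_DC[6] = {
  37.0 / 378.0 - 2825.0 / 27648.0, 0.0,
  250.0 / 621.0 - 18575.0 / 48384.0,
  125.0 / 594.0 - 13525.0 / 55296.0,
  -277.0 / 14336.0,
  512.0 / 1771.0 - 0.25};

#define MAXDIM 8

// status codes: 0 ok, 1 step underflow, 2 max steps exceeded,
//               3 leaflet contact (Z guard), 4 non-finite state
template <typename RHS, typename EMIT>
static int ck_integrate(RHS rhs, EMIT emit, int n, double* y,
                        double t0, double t1, double rtol, const double* atol,
                        double hmax, double hmin, double zguard, bool use_zguard,
                        long max_steps, long* steps_taken) {
  double t = t0;
  double h = std::min(hmax, (t1 - t0));
  double k[6][MAXDIM], ytmp[MAXDIM], yerr[MAXDIM], ynew[MAXDIM];
  long nst = 0;
  while (t < t1) {
    if (h > t1 - t) h = t1 - t;
    rhs(t, y, k[0]);
    for (int s = 1; s < 6; ++s) {
      for (int i = 0; i < n; ++i) {
        double acc = 0.0;
        for (int j = 0; j < s; ++j) acc += CK_B[s][j] * k[j][i];
        ytmp[i] = y[i] + h * acc;
      }
      rhs(t + CK_A[s] * h, ytmp, k[s]);
    }
    double err = 0.0;
    for (int i = 0; i < n; ++i) {
      double acc = 0.0, eacc = 0.0;
      for (int s = 0; s < 6; ++s) { acc += CK_C[s] * k[s][i]; eacc += CK_DC[s] * k[s][i]; }
      ynew[i] = y[i] + h * acc;
      yerr[i] = h * eacc;
      double sc = atol[i] + rtol * std::fabs(y[i]);
      double e = yerr[i] / sc;
      err += e * e;
    }
    err = std::sqrt(err / n);
    if (!std::isfinite(err)) {
      h *= 0.1;
      if (h < hmin) return 4;
      continue;
    }
    if (err <= 1.0) {
      // accept
      for (int i = 0; i < n; ++i) {
        if (!std::isfinite(ynew[i])) return 4;
      }
      if (use_zguard && ynew[0] <= zguard) return 3;
      emit(t, y, t + h, ynew);
      t += h;
      for (int i = 0; i < n; ++i) y[i] = ynew[i];
      double fac = 0.9 * std::pow(std::max(err, 1e-12), -0.2);
      h *= std::min(5.0, std::max(0.2, fac));
      if (h > hmax) h = hmax;
    } else {
      double fac = 0.9 * std::pow(err, -0.25);
      h *= std::max(0.1, fac);
      if (h < hmin) return 1;
    }
    if (++nst > max_steps) { *steps_taken += nst; return 2; }
  }
  *steps_taken += nst;
  return 0;
}

static void integ_error(int status, double t_hint) {
  if (status == 1) stop("integrator step underflow near t = %g s", t_hint);
  if (status == 2) stop("integrator exceeded the step budget near t = %g s", t_hint);
  if (status == 3) stop("mechanical failure: leaflet contact (Z reached -Delta/2) near t = %g s", t_hint);
  if (status == 4) stop("numerical error: non-finite state near t = %g s", t_hint);
}

// ---------------------------------------------------------------------------
// Mechanical steady cycle
// ---------------------------------------------------------------------------

struct MechRHS {
  const BLS* b;
  double PA, w, Qm;
  inline void operator()(double t, const double* y, double* dy) const {
    double Z = y[0], U = y[1], ng = y[2];
    double a2 = b->a * b->a;
    double zz = a2 + Z * Z;
    double S = M_PI * zz;
    double vol = M_PI * a2 * b->Delta + M_PI * Z * (a2 + Z * Z / 3.0);
    double rc = 2.0 * Z / zz;        // signed curvature 1/R(Z)
    double arc = std::fabs(rc);
    double Pin = ng * b->Rg * b->T / vol;
    double PM = b->pm_at(Z);
    double Ps = b->ks * rc * (S - b->S0) / b->S0;
    double Pec = -(b->S0 / S) * Qm * Qm / (2.0 * b->eps0 * b->epsr);
    double Pv = -4.0 * U * arc * (3.0 * b->delta0 * b->mus * arc + b->mul);
    double brac = Pin + PM - b->P0 - Ps + Pec + PA * std::sin(w * t) + Pv;
    dy[0] = U;
    dy[1] = -1.5 * rc * U * U + arc * brac / b->rhol;
    dy[2] = 2.0 * S * b->Dgl / b->xi * (b->Cg - Pin / b->kH);
  }
};

struct CycleStore {
  std::vector<double> t, Z, ng;
  void clear() { t.clear(); Z.clear(); ng.clear(); }
};

// [[Rcpp::export]]
List mech_cycle_cpp(double PA, double Qm, List params, double f,
                    double rtol, int max_cycles, double conv_tol,
                    int nsamples, long max_steps_per_cycle) {
  BLS b = make_bls(params);
  if (b.pm.empty()) stop("params carry no molecular-pressure table");
  MechRHS rhs{&b, PA, 2.0 * M_PI * f, Qm};
  double T = 1.0 / f;
  double y[3];
  y[0] = equilibrium_Z(Qm, b);
  y[1] = 0.0;
  double a2 = b.a * b.a;
  double vol0 = M_PI * a2 * b.Delta + M_PI * y[0] * (a2 + y[0] * y[0] / 3.0);
  y[2] = b.P0 * vol0 / (b.Rg * b.T);
  double atol[3] = {1e-16, 1e-6, 1e-28};
  double zguard = -0.4999 * b.Delta;
  double hmax = T / 40.0, hmin = 1e-17;

  CycleStore st;
  double prev_zmin = y[0], prev_zmax = y[0];
  bool converged = false;
  int cyc = 0;
  long nsteps = 0;
  for (cyc = 0; cyc < max_cycles; ++cyc) {
    st.clear();
    st.t.push_back(cyc * T); st.Z.push_back(y[0]); st.ng.push_back(y[2]);
    double zmin = y[0], zmax = y[0];
    auto emit = [&](double, const double*, double tn, const double* yn) {
      st.t.push_back(tn); st.Z.push_back(yn[0]); st.ng.push_back(yn[2]);
      if (yn[0] < zmin) zmin = yn[0];
      if (yn[0] > zmax) zmax = yn[0];
    };
    int status = ck_integrate(rhs, emit, 3, y, cyc * T, (cyc + 1) * T,
                              rtol, atol, hmax, hmin, zguard, true,
                              max_steps_per_cycle, &nsteps);
    integ_error(status, st.t.back());
    // scale: oscillation span for driven cycles, |Z| itself for the
    // (near-constant) undriven equilibrium
    double span = std::max(zmax - zmin,
                           std::max(std::fabs(zmax), std::fabs(zmin)));
    span = std::max(span, 1e-15);
    double dmin = std::fabs(zmin - prev_zmin), dmax = std::fabs(zmax - prev_zmax);
    if (cyc > 0 && std::max(dmin, dmax) / span < conv_tol) {
      converged = true;
      ++cyc;
      break;
    }
    prev_zmin = zmin; prev_zmax = zmax;
  }

  // resample the last stored cycle onto a uniform grid over [0, T)
  int ncyc_done = converged ? cyc : max_cycles;
  double tstart = (ncyc_done - 1) * T;
  NumericVector ts(nsamples), Zs(nsamples), ngs(nsamples);
  size_t j = 0;
  for (int i = 0; i < nsamples; ++i) {
    double tt = tstart + (double)i / nsamples * T;
    while (j + 1 < st.t.size() && st.t[j + 1] < tt) ++j;
    double t0 = st.t[j], t1 = st.t[j + 1];
    double fz = (tt - t0) / std::max(t1 - t0, 1e-300);
    ts[i] = tt - tstart;
    Zs[i] = st.Z[j] * (1.0 - fz) + st.Z[j + 1] * fz;
    ngs[i] = st.ng[j] * (1.0 - fz) + st.ng[j + 1] * fz;
  }
  return List::create(_["t"] = ts, _["Z"] = Zs, _["ng"] = ngs,
                      _["converged"] = converged, _["ncycles"] = ncyc_done,
                      _["nsteps"] = (double)nsteps);
}

// ---------------------------------------------------------------------------
// Pulsed-protocol segmentation shared by both integrators
// ---------------------------------------------------------------------------

struct Segment { double t0, t1; bool on; };

static std::vector<Segment> protocol_segments(double onset, double duration,
                                              double prf, double dc,
                                              double tend) {
  std::vector<Segment> seg;
  double eps = 1e-15;
  if (onset > eps) seg.push_back({0.0, std::min(onset, tend), false});
  if (tend > onset && duration > 0.0 && dc > 0.0) {
    double tstop = std::min(onset + duration, tend);
    if (dc >= 1.0 - 1e-12) {
      seg.push_back({onset, tstop, true});
    } else {
      double Tp = 1.0 / prf, ton = dc / prf;
      for (double t0 = onset; t0 < tstop - eps; t0 += Tp) {
        double aend = std::min(t0 + ton, tstop);
        if (aend > t0 + eps) seg.push_back({t0, aend, true});
        double bend = std::min(t0 + Tp, tstop);
        if (bend > aend + eps) seg.push_back({aend, bend, false});
      }
    }
    if (tend > tstop + eps) seg.push_back({tstop, tend, false});
  } else if (tend > onset + eps) {
    seg.push_back({onset, tend, false});
  }
  return seg;
}

// helper: emit-to-uniform-grid recorder
struct GridRec {
  double dt_out;
  int nout, dim;
  std::vector<double>* cols;  // dim arrays of length nout
  std::vector<double>* tvec;
  int next;
  void record(double t0, const double* y0, double t1, const double* y1) {
    while (next < nout) {
      double tt = next * dt_out;
      if (tt > t1 + 1e-18) break;
      double f = (t1 > t0) ? (tt - t0) / (t1 - t0) : 0.0;
      if (f < 0.0) f = 0.0;
      if (f > 1.0) f = 1.0;
      (*tvec)[next] = tt;
      for (int d = 0; d < dim; ++d)
        cols[d][next] = y0[d] * (1.0 - f) + y1[d] * f;
      ++next;
    }
  }
};

// ---------------------------------------------------------------------------
// Full NBLS co-integration oracle (voltage-form membrane + mechanics)
// ---------------------------------------------------------------------------

struct NblsRHS {
  const BLS* b;
  const RS* r;
  double PA, w;
  // y = Z, U, ng, Vm(mV), m, h, n, p
  inline void operator()(double t, const double* y, double* dy) const {
    double Z = y[0], U = y[1], ng = y[2], V = y[3];
    double m = y[4], h = y[5], n = y[6], p = y[7];
    double a2 = b->a * b->a;
    double zz = a2 + Z * Z;
    double S = M_PI * zz;
    double vol = M_PI * a2 * b->Delta + M_PI * Z * (a2 + Z * Z / 3.0);
    double rc = 2.0 * Z / zz;
    double arc = std::fabs(rc);
    double Cm = cm_of_Z(Z, b->a, b->Delta, b->Cm0);
    double Qm = Cm * V * 1e-3;
    double Pin = ng * b->Rg * b->T / vol;
    double PM = b->pm_at(Z);
    double Ps = b->ks * rc * (S - b->S0) / b->S0;
    double Pec = -(b->S0 / S) * Qm * Qm / (2.0 * b->eps0 * b->epsr);
    double Pv = -4.0 * U * arc * (3.0 * b->delta0 * b->mus * arc + b->mul);
    double brac = Pin + PM - b->P0 - Ps + Pec + PA * std::sin(w * t) + Pv;
    dy[0] = U;
    dy[1] = -1.5 * rc * U * U + arc * brac / b->rhol;
    dy[2] = 2.0 * S * b->Dgl / b->xi * (b->Cg - Pin / b->kH);
    double dCmdt = dcm_dZ(Z, b->a, b->Delta, b->Cm0) * U;
    double Itot = i_mem(V, m, h, n, p, *r);
    dy[3] = -(V * dCmdt + 1e3 * Itot) / Cm;   // mV/s
    double al[4], be[4];
    hh_rates(V, *r, al, be);
    dy[4] = al[0] * (1.0 - m) - be[0] * m;
    dy[5] = al[1] * (1.0 - h) - be[1] * h;
    dy[6] = al[2] * (1.0 - n) - be[2] * n;
    dy[7] = al[3] * (1.0 - p) - be[3] * p;
  }
};

// [[Rcpp::export]]
List nbls_cpp(double PA, double f, double prf, double dc, double onset,
              double duration, double tend, List params, List rs,
              double rtol, double dt_out, double max_steps_millions) {
  BLS b = make_bls(params);
  RS r = make_rs(rs);
  if (b.pm.empty()) stop("params carry no molecular-pressure table");
  List rest = rs_steady_cpp(rs);
  double y[8];
  double Vm0 = rest["Vm0"];
  // self-consistent rest: mechanical equilibrium at the charge implied by
  // the deflected capacitance, Qm = Cm(Z0) Vm0 (fixed-point iteration)
  double Qm0 = r.Cm0 * Vm0 * 1e-3, Z0 = 0.0;
  for (int it = 0; it < 100; ++it) {
    Z0 = equilibrium_Z(Qm0, b);
    double Qnew = cm_of_Z(Z0, b.a, b.Delta, b.Cm0) * Vm0 * 1e-3;
    if (std::fabs(Qnew - Qm0) < 1e-12 * std::fabs(Qm0)) { Qm0 = Qnew; break; }
    Qm0 = Qnew;
  }
  y[0] = Z0;
  y[1] = 0.0;
  double a2 = b.a * b.a;
  double vol0 = M_PI * a2 * b.Delta + M_PI * y[0] * (a2 + y[0] * y[0] / 3.0);
  y[2] = b.P0 * vol0 / (b.Rg * b.T);
  y[3] = Vm0;
  y[4] = rest["m0"]; y[5] = rest["h0"]; y[6] = rest["n0"]; y[7] = rest["p0"];

  double atol[8] = {1e-16, 1e-6, 1e-28, 1e-7, 1e-9, 1e-9, 1e-9, 1e-9};
  double zguard = -0.4999 * b.Delta;
  double T = 1.0 / f;

  int nout = (int)std::floor(tend / dt_out) + 1;
  std::vector<double> tvec(nout);
  std::vector<double> cols[8];
  for (int d = 0; d < 8; ++d) cols[d].assign(nout, NA_REAL);
  GridRec rec{dt_out, nout, 8, cols, &tvec, 0};
  // record initial point
  rec.record(0.0, y, 0.0, y);

  long nsteps = 0;
  long budget = (long)(max_steps_millions * 1e6);
  std::vector<Segment> seg = protocol_segments(onset, duration, prf, dc, tend);
  for (size_t s = 0; s < seg.size(); ++s) {
    NblsRHS rhs{&b, &r, seg[s].on ? PA : 0.0, 2.0 * M_PI * f};
    double hmax = seg[s].on ? T / 40.0 : 2e-5;
    auto emit = [&](double t0, const double* y0, double t1, const double* y1) {
      rec.record(t0, y0, t1, y1);
    };
    int status = ck_integrate(rhs, emit, 8, y, seg[s].t0, seg[s].t1,
                              rtol, atol, hmax, 1e-17, zguard, true,
                              budget, &nsteps);
    integ_error(status, seg[s].t0);
    if (nsteps > budget) stop("oracle integration exceeded its step budget");
    Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["t"] = NumericVector(tvec.begin(), tvec.end()),
    _["Z"] = NumericVector(cols[0].begin(), cols[0].end()),
    _["ng"] = NumericVector(cols[2].begin(), cols[2].end()),
    _["Vm"] = NumericVector(cols[3].begin(), cols[3].end()),
    _["m"] = NumericVector(cols[4].begin(), cols[4].end()),
    _["h"] = NumericVector(cols[5].begin(), cols[5].end()),
    _["n"] = NumericVector(cols[6].begin(), cols[6].end()),
    _["p"] = NumericVector(cols[7].begin(), cols[7].end()),
    _["nsteps"] = (double)nsteps);
}

// ---------------------------------------------------------------------------
// Effective-variable (cycle-averaged) integration of the charge-cast system
// ---------------------------------------------------------------------------

struct TableSlice {
  // 1D slices along the charge axis at the protocol pressure amplitude
  const double* q;   // increasing grid, C/m^2
  int nq;
  const double* invcm;        // <1/Cm>_T, m^2/F
  const double* rates[8];     // effective rate constants, 1/s
  double interp(const double* v, double Qm) const {
    if (Qm <= q[0]) return v[0];
    if (Qm >= q[nq - 1]) return v[nq - 1];
    int lo = 0, hi = nq - 1;
    while (hi - lo > 1) { int mid = (lo + hi) / 2; if (q[mid] <= Qm) lo = mid; else hi = mid; }
    double f = (Qm - q[lo]) / (q[lo + 1] - q[lo]);
    return v[lo] * (1.0 - f) + v[lo + 1] * f;
  }
};

struct SonicRHS {
  const RS* r;
  const TableSlice* tab;
  bool on;
  // y = Qm, m, h, n, p
  inline void operator()(double, const double* y, double* dy) const {
    double Qm = y[0], m = y[1], h = y[2], n = y[3], p = y[4];
    double al[4], be[4];
    double V;
    if (on) {
      V = Qm * tab->interp(tab->invcm, Qm) * 1e3;  // effective potential, mV
      for (int k = 0; k < 4; ++k) {
        al[k] = tab->interp(tab->rates[2 * k], Qm);
        be[k] = tab->interp(tab->rates[2 * k + 1], Qm);
      }
    } else {
      V = Qm / r->Cm0 * 1e3;
      hh_rates(V, *r, al, be);
    }
    dy[0] = -i_mem(V, m, h, n, p, *r);
    dy[1] = al[0] * (1.0 - m) - be[0] * m;
    dy[2] = al[1] * (1.0 - h) - be[1] * h;
    dy[3] = al[2] * (1.0 - n) - be[2] * n;
    dy[4] = al[3] * (1.0 - p) - be[3] * p;
  }
};

// [[Rcpp::export]]
List sonic_cpp(double prf, double dc, double onset, double duration,
               double tend, List rs, NumericVector qgrid,
               NumericVector invcm_slice, NumericMatrix rates_slice,
               double rtol, double dt_out) {
  RS r = make_rs(rs);
  bool have_table = qgrid.size() > 0;
  TableSlice tab;
  if (have_table) {
    tab.q = &qgrid[0];
    tab.nq = qgrid.size();
    tab.invcm = &invcm_slice[0];
    for (int k = 0; k < 8; ++k) tab.rates[k] = &rates_slice(0, k);
  }
  List rest = rs_steady_cpp(rs);
  double y[5];
  y[0] = rest["Qm0"];
  y[1] = rest["m0"]; y[2] = rest["h0"]; y[3] = rest["n0"]; y[4] = rest["p0"];
  double atol[5] = {1e-12, 1e-9, 1e-9, 1e-9, 1e-9};

  int nout = (int)std::floor(tend / dt_out) + 1;
  std::vector<double> tvec(nout);
  std::vector<double> cols[5];
  for (int d = 0; d < 5; ++d) cols[d].assign(nout, NA_REAL);
  std::vector<int> onflag(nout, 0);
  GridRec rec{dt_out, nout, 5, cols, &tvec, 0};
  rec.record(0.0, y, 0.0, y);

  long nsteps = 0;
  std::vector<Segment> seg = protocol_segments(onset, duration, prf, dc, tend);
  for (size_t s = 0; s < seg.size(); ++s) {
    if (seg[s].on && !have_table) stop("protocol has ultrasound-ON intervals but no lookup table was supplied");
    SonicRHS rhs{&r, &tab, seg[s].on};
    int mark_from = rec.next;
    auto emit = [&](double t0, const double* y0, double t1, const double* y1) {
      rec.record(t0, y0, t1, y1);
    };
    int status = ck_integrate(rhs, emit, 5, y, seg[s].t0, seg[s].t1,
                              rtol, atol, 1e-4, 1e-15, 0.0, false,
                              100000000L, &nsteps);
    integ_error(status, seg[s].t0);
    if (seg[s].on) for (int i = mark_from; i < rec.next; ++i) onflag[i] = 1;
  }

  return List::create(
    _["t"] = NumericVector(tvec.begin(), tvec.end()),
    _["Qm"] = NumericVector(cols[0].begin(), cols[0].end()),
    _["m"] = NumericVector(cols[1].begin(), cols[1].end()),
    _["h"] = NumericVector(cols[2].begin(), cols[2].end()),
    _["n"] = NumericVector(cols[3].begin(), cols[3].end()),
    _["p"] = NumericVector(cols[4].begin(), cols[4].end()),
    _["on"] = IntegerVector(onflag.begin(), onflag.end()),
    _["nsteps"] = (double)nsteps);
}
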