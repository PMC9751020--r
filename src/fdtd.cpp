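// 2D first-order acoustic FDTD on a staggered grid with split-field PML.
//
//   dp/dt = -rho c^2 div(u) - sigma_a p      (sigma_a = 2 c alpha, tissue loss)
//   du/dt = -(1/rho) grad(p)
//
// Pressure lives at cell centres, velocities at faces. Pixel (i, j) covers
// [i dx, (i+1) dx) x [j dx, (j+1) dx) with the centre at ((i+.5) dx, (j+.5) dx).
// The source is a hard source (pressure override) on a pixel mask. Maximum
// |p| and a running sum of p^2 (for time-averaged intensity) are accumulated
// per pixel; full time series are stored only at requested trace pixels.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export]]
List fdtd_core(NumericMatrix cmap, NumericMatrix rhomap, NumericMatrix alphanp,
               IntegerVector src_idx, double amp, double freq, double on_time,
               double dx, double dt, int nsteps, int pml, double pml_r0,
               int pml_m, int rec_start, int rec_end, IntegerVector trace_idx,
               bool track_energy, double ramp_cycles) {
  const int nx = cmap.nrow(), ny = cmap.ncol();
  const int N = nx * ny;
  std::vector<double> px(N, 0.0), py(N, 0.0), p(N, 0.0);
  std::vector<double> ux(N, 0.0), uy(N, 0.0);   // ux(i,j) at (i+1/2, j); last row unused
  std::vector<double> kap(N), rhoc(N), siga(N), maxp(N, 0.0), sumsq(N, 0.0);

  double cmax = 0.0;
  for (int k = 0; k < N; ++k) {
    double c = cmap[k], rho = rhomap[k];
    kap[k] = rho * c * c;
    rhoc[k] = rho * c;
    siga[k] = 2.0 * c * alphanp[k];
    if (c > cmax) cmax = c;
  }
  if (dt > dx / (cmax * std::sqrt(2.0)))
    stop("CFL violation: dt = %g exceeds dx/(c_max*sqrt(2)) = %g", dt,
         dx / (cmax * std::sqrt(2.0)));

  // PML damping profiles (1/s) at integer and half positions
  std::vector<double> sgx(nx, 0.0), sgxh(nx, 0.0), sgy(ny, 0.0), sgyh(ny, 0.0);
  if (pml > 0) {
    double L = pml * dx;
    double smax = (pml_m + 1) * cmax * std::log(1.0 / pml_r0) / (2.0 * L);
    auto prof = [&](double pos, int n) {
      // pos in pixels from the grid edge (0 .. n)
      double d = 0.0;
      if (pos < pml) d = (pml - pos) / pml;
      else if (pos > n - pml) d = (pos - (n - pml)) / pml;
      return smax * std::pow(d, (double)pml_m);
    };
    for (int i = 0; i < nx; ++i) { sgx[i] = prof(i + 0.5, nx); sgxh[i] = prof(i + 1.0, nx); }
    for (int j = 0; j < ny; ++j) { sgy[j] = prof(j + 0.5, ny); sgyh[j] = prof(j + 1.0, ny); }
  }

  const int ntr = trace_idx.size();
  NumericMatrix traces(ntr > 0 ? nsteps : 0, ntr);
  NumericVector energy(track_energy ? nsteps : 0);
  const double w = 2.0 * M_PI * freq;
  const double inv_dx = 1.0 / dx;
  long nrec = 0;

  for (int n = 0; n < nsteps; ++n) {
    // velocity update: u(t + dt/2) from p(t)
    for (int j = 0; j < ny; ++j) {
      const int off = nx * j;
      for (int i = 0; i < nx - 1; ++i) {
        int k = off + i;
        double rho_f = 0.5 * (rhomap[k] + rhomap[k + 1]);
        double s = sgxh[i];
        ux[k] = (ux[k] * (1.0 - 0.5 * dt * s)
                 - dt * (p[k + 1] - p[k]) * inv_dx / rho_f)
                / (1.0 + 0.5 * dt * s);
      }
    }
    for (int j = 0; j < ny - 1; ++j) {
      const int off = nx * j;
      double s = sgyh[j];
      for (int i = 0; i < nx; ++i) {
        int k = off + i;
        double rho_f = 0.5 * (rhomap[k] + rhomap[k + nx]);
        uy[k] = (uy[k] * (1.0 - 0.5 * dt * s)
                 - dt * (p[k + nx] - p[k]) * inv_dx / rho_f)
                / (1.0 + 0.5 * dt * s);
      }
    }
    // pressure update: p(t + dt) from u(t + dt/2)
    for (int j = 0; j < ny; ++j) {
      const int off = nx * j;
      for (int i = 0; i < nx; ++i) {
        int k = off + i;
        double dux = (i > 0) ? (ux[k] - ux[k - 1]) : ux[k];
        if (i == nx - 1) dux = -ux[k - 1];
        double duy = (j > 0) ? (uy[k] - uy[k - nx]) : uy[k];
        if (j == ny - 1) duy = -uy[k - nx];
        double sx = sgx[i] + siga[k], sy = sgy[j] + siga[k];
        px[k] = (px[k] * (1.0 - 0.5 * dt * sx) - dt * kap[k] * dux * inv_dx)
                / (1.0 + 0.5 * dt * sx);
        py[k] = (py[k] * (1.0 - 0.5 * dt * sy) - dt * kap[k] * duy * inv_dx)
                / (1.0 + 0.5 * dt * sy);
        p[k] = px[k] + py[k];
      }
    }
    // hard source, smoothly ramped over the first ramp_cycles periods to
    // avoid a broadband onset transient (its focusing converges poorly in dx)
    double tnew = (n + 1) * dt;
    if (tnew <= on_time && amp != 0.0) {
      double env = 1.0;
      if (ramp_cycles > 0.0 && freq > 0.0) {
        double tr = ramp_cycles / freq;
        if (tnew < tr) { double s = std::sin(0.5 * M_PI * tnew / tr); env = s * s; }
      }
      double val = env * amp * std::sin(w * tnew);
      for (int s = 0; s < src_idx.size(); ++s) {
        int k = src_idx[s];
        px[k] = 0.5 * val; py[k] = 0.5 * val; p[k] = val;
      }
    }
    // accumulate
    for (int k = 0; k < N; ++k) {
      double ap = std::fabs(p[k]);
      if (ap > maxp[k]) maxp[k] = ap;
    }
    if (n >= rec_start && n < rec_end) {
      for (int k = 0; k < N; ++k) sumsq[k] += p[k] * p[k];
      ++nrec;
    }
    for (int s = 0; s < ntr; ++s) traces(n, s) = p[trace_idx[s]];
    if (track_energy) {
      double E = 0.0;
      for (int k = 0; k < N; ++k) {
        E += p[k] * p[k] / (2.0 * kap[k]);
        E += 0.5 * rhomap[k] * (ux[k] * ux[k] + uy[k] * uy[k]);
      }
      energy[n] = E * dx * dx;
    }
    if ((n & 255) == 0) {
      if (!std::isfinite(p[N / 2]) || !std::isfinite(p[0]))
        stop("numerical instability: non-finite pressure at step %d", n);
      Rcpp::checkUserInterrupt();
    }
  }
  for (int k = 0; k < N; ++k)
    if (!std::isfinite(p[k]))
      stop("numerical instability: non-finite pressure at final step");

  NumericMatrix maxp_m(nx, ny), int_m(nx, ny);
  for (int k = 0; k < N; ++k) {
    maxp_m[k] = maxp[k];
    int_m[k] = (nrec > 0) ? (sumsq[k] / (double)nrec) / rhoc[k] : 0.0;
  }
  return List::create(_["max_pressure"] = maxp_m, _["avg_intensity"] = int_m,
                      _["n_recorded"] = (double)nrec, _["traces"] = traces,
                      _["energy"] = energy, _["dt"] = dt,
                      _["nsteps"] = nsteps);
}
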