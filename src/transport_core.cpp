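#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Explicit finite-difference stepper for the depth-averaged ATP transport
// equation
//   d(phi)/dt + ubar(t) d(phi)/dz = D d2(phi)/dx2 + Deff(t) d2(phi)/dz2
// on a uniform nx x nz grid (x transverse in [0, W], z axial in [0, L]).
//
// Discretization: first-order upwind for the axial convection term (ubar >=
// 0, so a backward difference), second-order central differences for both
// diffusion terms.  Boundary conditions: Dirichlet linear inlet profile at
// z = 0 re-evaluated every step from the instantaneous stream-width
// fraction eps(t); mirror (no-flux) ghost nodes at x = 0 and x = W;
// zero-gradient closure at the truncated outflow z = L.
//
// Inputs ubar, deff, eps are sampled at every time level t_k = k * dt
// (length nsteps + 1); the value at t_k advances the step k -> k + 1.
//
// Recorded outputs:
//  - bilinear-interpolated time series at observation points every
//    out_every steps (obs_i0/obs_wx: lower x-node and weight; obs_j0/obs_wz
//    likewise in z),
//  - full-field snapshots at the requested step indices,
//  - running min/max of the field over all nodes and steps (discrete
//    maximum-principle monitor),
//  - max absolute field change over a trailing window of sec_every output
//    frames (settling monitor; with out_dt * sec_every = 1 s this is the
//    per-second change).
// [[Rcpp::export]]
List transport_fd_core(int nx, int nz, double dx, double dz, double dt,
                       NumericVector ubar, NumericVector deff,
                       NumericVector eps, double D, double phi0, double W,
                       int out_every, IntegerVector snap_steps,
                       IntegerVector obs_i0, NumericVector obs_wx,
                       IntegerVector obs_j0, NumericVector obs_wz,
                       int sec_every) {
  const int nsteps = ubar.size() - 1;
  const int nnode = nx * nz;
  const int nobs = obs_i0.size();
  const int nout = nsteps / out_every + 1;  // caller aligns nsteps
  std::vector<double> phi(nnode, 0.0), nxt(nnode, 0.0);
  NumericMatrix series(nout, nobs);
  NumericVector t_out(nout);
  NumericVector settle(nout);
  std::fill(settle.begin(), settle.end(), NA_REAL);
  const int nsnap = snap_steps.size();
  NumericVector snaps(Dimension(nx, nz, std::max(nsnap, 1)));
  double phimin = 0.0, phimax = 0.0;
  // ring buffer of output frames for the settling monitor
  std::vector<std::vector<double> > ring;
  if (sec_every > 0) ring.assign(sec_every, std::vector<double>(nnode, 0.0));

  const double idz = 1.0 / dz, idx2 = 1.0 / (dx * dx), idz2 = 1.0 / (dz * dz);

  // inlet row at z = 0 for stream-width fraction e
  auto set_inlet = [&](double e) {
    for (int i = 0; i < nx; ++i) {
      double x = i * dx;
      double v = 0.0;
      if (e > 0.0 && x <= e * W) v = phi0 * (1.0 - x / (e * W));
      phi[i] = v;  // j = 0 row is i + nx*0
    }
  };

  auto record = [&](int k, int m) {
    t_out[m] = k * dt;
    for (int o = 0; o < nobs; ++o) {
      int i0 = obs_i0[o], j0 = obs_j0[o];
      double wx = obs_wx[o], wz = obs_wz[o];
      int i1 = std::min(i0 + 1, nx - 1), j1 = std::min(j0 + 1, nz - 1);
      double v00 = phi[i0 + nx * j0], v10 = phi[i1 + nx * j0];
      double v01 = phi[i0 + nx * j1], v11 = phi[i1 + nx * j1];
      series(m, o) = (1 - wx) * ((1 - wz) * v00 + wz * v01) +
                     wx * ((1 - wz) * v10 + wz * v11);
    }
    if (sec_every > 0) {
      int slot = m % sec_every;
      if (m >= sec_every) {
        double d = 0.0;
        const std::vector<double>& old = ring[slot];
        for (int q = 0; q < nnode; ++q)
          d = std::max(d, std::fabs(phi[q] - old[q]));
        settle[m] = d;
      }
      std::copy(phi.begin(), phi.end(), ring[slot].begin());
    }
  };

  set_inlet(eps[0]);
  int snap_ptr = 0;
  auto maybe_snap = [&](int k) {
    while (snap_ptr < nsnap && snap_steps[snap_ptr] == k) {
      for (int j = 0; j < nz; ++j)
        for (int i = 0; i < nx; ++i)
          snaps[i + nx * j + nnode * snap_ptr] = phi[i + nx * j];
      ++snap_ptr;
    }
  };
  record(0, 0);
  maybe_snap(0);

  int bad_step = -1;
  for (int k = 0; k < nsteps && bad_step < 0; ++k) {
    const double u = ubar[k], De = deff[k];
    double lo = phi[0], hi = phi[0];
    // interior + boundaries in x; j = 0 is Dirichlet (skipped)
    for (int j = 1; j < nz; ++j) {
      const int row = nx * j;
      for (int i = 0; i < nx; ++i) {
        const double c = phi[i + row];
        const double cl = (i > 0) ? phi[i - 1 + row] : phi[i + 1 + row];
        const double cr = (i < nx - 1) ? phi[i + 1 + row] : phi[i - 1 + row];
        const double cb = phi[i + row - nx];                       // j - 1
        const double cf = (j < nz - 1) ? phi[i + row + nx] : c;    // j + 1 (outflow ghost)
        const double rhs = -u * (c - cb) * idz
                           + D * (cl - 2.0 * c + cr) * idx2
                           + De * (cf - 2.0 * c + cb) * idz2;
        const double v = c + dt * rhs;
        nxt[i + row] = v;
        if (v < lo) lo = v;
        if (v > hi) hi = v;
      }
    }
    if (!std::isfinite(lo) || !std::isfinite(hi)) { bad_step = k + 1; break; }
    phimin = std::min(phimin, lo);
    phimax = std::max(phimax, hi);
    phi.swap(nxt);
    set_inlet(eps[k + 1]);
    if ((k + 1) % out_every == 0) record(k + 1, (k + 1) / out_every);
    maybe_snap(k + 1);
  }

  return List::create(_["t"] = t_out, _["series"] = series,
                      _["snapshots"] = snaps, _["phimin"] = phimin,
                      _["phimax"] = phimax, _["settle"] = settle,
                      _["bad_step"] = bad_step);
}
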